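# Independent oracles, implemented from first principles so they share no
# code with the package internals.

# reverse complement via character translation
oracleRevcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# the standard genetic code, written out
oracleCodonTable <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# codon-by-codon translation of the reverse complement, frame 1
oracleTranslateRev <- function(s) {
    rc <- oracleRevcomp(toupper(s))
    n <- (nchar(rc) %/% 3L) * 3L
    if (n == 0L) return("")
    codons <- substring(rc, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- oracleCodonTable[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

# exhaustive primer-placement scan: every (i, j) with the forward word at
# i and the reverse-complemented reverse word starting after the forward
# word ends; returns products on the given strand only
oraclePCRStrand <- function(template, fwd, rev, cap = 5000L) {
    rcRev <- oracleRevcomp(rev)
    L <- nchar(template)
    at <- function(word) {
        k <- nchar(word)
        which(vapply(seq_len(L - k + 1L),
                     function(i) substr(template, i, i + k - 1L) == word,
                     logical(1)))
    }
    fs <- at(fwd)
    rs <- at(rcRev)
    out <- NULL
    for (i in fs) for (j in rs) {
        if (j >= i + nchar(fwd)) {
            e <- j + nchar(rcRev) - 1L
            if (e - i + 1L <= cap)
                out <- rbind(out, c(start = i - 1L, end = e))
        }
    }
    out
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# plant a word into a template at a 1-based position
plantWord <- function(template, word, pos) {
    substr(template, pos, pos + nchar(word) - 1L) <- word
    template
}

# plain vector of SNP states, attributes dropped
bareStates <- function(x) { attributes(x) <- NULL; x }
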