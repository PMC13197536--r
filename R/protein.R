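#' Translate the reverse-complement frame 1 of a DNA sequence
#'
#' The skin color gene is read off the minus strand: the sequence is
#' reverse-complemented and translated from its first base with the
#' standard genetic code (the 3'-5' frame 1). The trailing partial codon
#' is dropped. Stop codons are rendered as \code{'*'} and translation
#' continues -- this is variant reconstruction, not ORF calling. Codons
#' containing a non-ACGT symbol translate to \code{'X'}.
#'
#' @param seq DNA sequence (character or \code{DNAString}), length >= 3.
#' @return Amino-acid string.
#' @examples
#' translateReverseFrame1("AGCAGCAGC")  # "AAA" (polyalanine)
#' translateReverseFrame1("CAT")        # "M"
#' @export
translateReverseFrame1 <- function(seq) {
    s <- if (is(seq, "DNAString")) as.character(seq) else {
        if (!is.character(seq) || length(seq) != 1L)
            stop("seq must be a single sequence")
        toupper(seq)
    }
    if (nchar(s) < 3L) stop("need at least one full codon")
    s <- gsub("[^ACGT]", "N", s)
    rc <- reverseComplement(DNAString(s))
    rc <- subseq(rc, 1L, (length(rc) %/% 3L) * 3L)
    as.character(translate(rc, if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Longest polyalanine tract of a protein
#'
#' @param protein Amino-acid string (one-letter code).
#' @return List with \code{start} (0-based index, \code{NA} when the
#'   protein has no alanine) and \code{length} (residues; 0 when absent).
#'   The longest run wins; ties go to the leftmost.
#' @examples
#' polyalanineTract("MKAAAAQ")  # start 2, length 4
#' @export
polyalanineTract <- function(protein) {
    if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
        stop("protein must be a single non-empty string")
    r <- rle(strsplit(protein, "")[[1L]] == "A")
    if (!any(r$values)) return(list(start = NA_integer_, length = 0L))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths            # 0-based
    aRuns <- which(r$values)
    best <- aRuns[which.max(r$lengths[aRuns])]  # first max = leftmost
    list(start = as.integer(starts[best]),
         length = as.integer(r$lengths[best]))
}

#' Residue encoded at the two variable amino acid positions
#'
#' At the non-synonymous SNPs of the skin color gene (SNP3, position 195;
#' SNP4, position 146), guanine specifies histidine and adenine specifies
#' tyrosine.
#'
#' @param base \code{"G"} or \code{"A"}.
#' @return \code{"H"} or \code{"Y"}.
#' @export
variantResidue <- function(base) {
    if (!is.character(base) || length(base) != 1L)
        stop("base must be a single character")
    switch(toupper(base),
        G = "H",
        A = "Y",
        stop(structure(class = c("apricotMAS_unknown_substitution",
                                 "error", "condition"),
             list(message = paste0("no substitution rule for base '",
                                   base, "' (expected G or A)"),
                  call = sys.call(-1L)))))
}

#' Protein variant encoded by an allele call
#'
#' Maps the four named alleles to the four named protein variants and
#' renders any other haplotype as a novel variant. Each AGC repeat unit
#' contributes one alanine, so the polyalanine length is
#' 4 + (ssr_size - 108) / 3 (anchored at four alanines for the 108 bp
#' allele). The variable residues come from the non-synonymous SNPs:
#' residue 195 from SNP3 and residue 146 from SNP4 (G -> H, A -> Y).
#'
#' When the repeat count is a whole number the surrogate allele sequence
#' is built and translated, and the tract is measured on the actual
#' protein; an SSR size that is not congruent to 108 modulo 3 would shift
#' the reading frame (never observed in the four named alleles) and is
#' flagged with a warning, with no sequence rendered.
#'
#' @param call An [AlleleCall-class] (see [assembleHaplotype()]).
#' @return A [ProteinVariant-class].
#' @examples
#' proteinVariant(assembleHaplotype(114, c("T", "T", "A", "G")))
#' @export
proteinVariant <- function(call) {
    stopifnot(is(call, "AlleleCall"))
    states <- snpStates(call)
    size <- ssrSize(call)
    nRep <- 4 + (size - 108) / 3
    name <- if (grepl("^Allele[1-4]$", alleleName(call)))
        sub("Allele", "Protein", alleleName(call)) else "novel"
    res195 <- variantResidue(states[["SNP3"]])
    res146 <- variantResidue(states[["SNP4"]])
    seqAA <- ""
    start <- NA_real_
    len <- nRep
    if (nRep != round(nRep)) {
        warning("SSR size ", size, " is not congruent to 108 modulo 3: ",
                "the reading frame would shift; no sequence rendered")
    } else if (nRep >= 2) {
        allele <- simulateAlleleSequence(
            alleleSpec(repeatCount = as.integer(nRep), snpStates = states))
        seqAA <- translateReverseFrame1(allele$sequence)
        tract <- polyalanineTract(seqAA)
        start <- tract$start
        len <- tract$length
    }
    new("ProteinVariant",
        variantName = name,
        sequence = seqAA,
        polyalaLength = as.numeric(len),
        polyalaStart = as.numeric(start),
        residue146 = res146,
        residue195 = res195)
}
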