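#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern countPattern translate subseq
NULL

.asSeqChar <- function(x) {
    if (is(x, "DNAString") || is(x, "DNAStringSet")) {
        if (is(x, "DNAStringSet")) {
            if (length(x) != 1L) stop("expected a single sequence")
            x <- x[[1L]]
        }
        return(as.character(x))
    }
    if (is.character(x) && length(x) == 1L) return(toupper(x))
    stop("expected a DNAString or a single character sequence")
}

.revcomp <- function(x) as.character(reverseComplement(DNAString(x)))

#' Built-in primer pairs
#'
#' \code{col1Primers()} is the fluorescently genotyped AGC-microsatellite
#' assay inside the AP2/ERF skin color gene (Col1); \code{snp4Primers()}
#' is the HRM assay for the non-synonymous SNP S3_22924316 (109 bp
#' amplicon).
#'
#' @return A [PrimerPair-class].
#' @export
col1Primers <- function() {
    new("PrimerPair", markerId = "Col1",
        forward = "CCCCATCACCACCTCCTGAT",
        reverse = "GGGAGAGGCATATCTGAGTCC",
        expectedSize = 114)
}

#' @rdname col1Primers
#' @export
snp4Primers <- function() {
    new("PrimerPair", markerId = "S3_22924316",
        forward = "TCCTGCTTCTTCTTCCTGATGA",
        reverse = "GCTCAAAGCAAGAAACAACAGC",
        expectedSize = 109)
}

#' Definitions of the four intragenic SNPs
#'
#' The four SNPs of the AP2/ERF gene on chromosome 3, with their 1-based
#' genomic positions, their 0-based offsets in the packaged surrogate
#' reference allele (Allele 1, the 'Currot'-type SSR108 state), and their
#' reference/alternative bases. SNP1 is the HRM-validated S3_22924169;
#' SNP3 and SNP4 are the non-synonymous His/Tyr sites.
#'
#' The surrogate reference is generated, not the published genomic
#' sequence (which is available only as a figure); its SNP offsets
#' preserve the genomic spacing up to a 1 bp adjustment at SNP4 required
#' to hold both non-synonymous sites at the first position of a
#' reverse-frame codon.
#'
#' @return data.frame with columns \code{label} (SNP1..SNP4),
#'   \code{snp_id}, \code{genomic_position}, \code{ref_offset} (0-based in
#'   the reference allele), \code{ref}, \code{alt}.
#' @export
snpDefinitions <- function() {
    data.frame(
        label = c("SNP1", "SNP2", "SNP3", "SNP4"),
        snp_id = c("S3_22924169", "S3_22924445",
                   "S3_22924252", "S3_22924316"),
        genomic_position = c(22924169L, 22924445L, 22924252L, 22924316L),
        ref_offset = c(315L, 591L, 398L, 461L),
        ref = c("C", "G", "A", "A"),
        alt = c("T", "T", "G", "G"),
        stringsAsFactors = FALSE
    )
}

#' The four named alleles of the AP2/ERF skin color gene
#'
#' Each allele is the joint state of the intragenic AGC microsatellite
#' (amplicon size in bp) and the four SNPs.
#'
#' @return data.frame with columns \code{allele}, \code{ssr_size},
#'   \code{SNP1..SNP4}.
#' @examples
#' alleleTable()
#' @export
alleleTable <- function() {
    data.frame(
        allele = paste0("Allele", 1:4),
        ssr_size = c(108L, 111L, 114L, 120L),
        SNP1 = c("C", "C", "T", "C"),
        SNP2 = c("G", "G", "T", "G"),
        SNP3 = c("A", "G", "A", "A"),
        SNP4 = c("A", "G", "G", "G"),
        stringsAsFactors = FALSE
    )
}

#' In-silico PCR with exact primer matching
#'
#' Finds every placement of the forward primer and of the
#' reverse-complemented reverse primer on a template and emits all
#' products in which the reverse-primer site begins after the forward
#' site ends, up to a length cap. Both template strands are searched; the
#' minus strand is scanned as the reverse complement of the template, and
#' minus-strand coordinates refer to that reverse-complemented sequence.
#' Primer annealing is exact (no mismatches or degeneracy), matching how
#' the assays were designed.
#'
#' @param template DNA sequence (character or \code{DNAString}).
#' @param primers A [PrimerPair-class].
#' @param maxProductLength Longest product emitted, bp.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open on the searched strand), \code{length}, \code{strand},
#'   \code{sequence}. Zero rows when there is no product.
#' @examples
#' pp <- col1Primers()
#' tmpl <- paste0("AAAA", pp@forward, "TTTTT",
#'                as.character(Biostrings::reverseComplement(
#'                    Biostrings::DNAString(pp@reverse))), "GGGG")
#' insilicoPCR(tmpl, pp)$length  # 46
#' @export
insilicoPCR <- function(template, primers, maxProductLength = 5000L) {
    stopifnot(is(primers, "PrimerPair"))
    tmpl <- .asSeqChar(template)
    if (grepl("[^ACGT]", tmpl))
        stop("template must be plain ACGT")
    rcRev <- .revcomp(primers@reverse)
    scan1 <- function(s, strand) {
        subj <- DNAString(s)
        f <- matchPattern(primers@forward, subj)
        r <- matchPattern(rcRev, subj)
        if (length(f) == 0L || length(r) == 0L) return(NULL)
        fs <- BiocGenerics::start(f)   # 1-based
        rs <- BiocGenerics::start(r)
        re <- BiocGenerics::end(r)
        out <- NULL
        for (i in fs) {
            keep <- rs >= i + nchar(primers@forward)
            ends <- re[keep]
            ends <- ends[ends - i + 1L <= maxProductLength]
            if (length(ends))
                out <- rbind(out, data.frame(start = i - 1L, end = ends,
                                             strand = strand))
        }
        out
    }
    res <- rbind(scan1(tmpl, "+"), scan1(.revcomp(tmpl), "-"))
    if (is.null(res))
        return(data.frame(start = integer(), end = integer(),
                          length = integer(), strand = character(),
                          sequence = character(),
                          stringsAsFactors = FALSE))
    res <- res[order(res$strand, res$start, res$end), , drop = FALSE]
    seqs <- character(nrow(res))
    rcTmpl <- .revcomp(tmpl)
    for (i in seq_len(nrow(res))) {
        s <- if (res$strand[i] == "+") tmpl else rcTmpl
        seqs[i] <- substr(s, res$start[i] + 1L, res$end[i])
    }
    data.frame(start = res$start, end = res$end,
               length = res$end - res$start,
               strand = res$strand, sequence = seqs,
               stringsAsFactors = FALSE, row.names = NULL)
}

# all maximal perfect tandem chains of `motif` in any phase:
# data.frame(start [0-based], count), one row per maximal chain
.allTandemRuns <- function(seq, motif) {
    k <- nchar(motif)
    rots <- unique(vapply(seq_len(k) - 1L, function(r)
        paste0(substr(motif, r + 1L, k), substr(motif, 1L, r)),
        character(1)))
    out <- NULL
    for (w in rots) {
        m <- gregexpr(w, seq, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        pos <- as.integer(m)
        brk <- c(TRUE, diff(pos) != k)
        grp <- cumsum(brk)
        starts <- tapply(pos, grp, min)
        counts <- tapply(pos, grp, length)
        out <- rbind(out, data.frame(start = as.integer(starts) - 1L,
                                     count = as.integer(counts)))
    }
    out
}

#' Locate the longest perfect tandem repeat of a motif
#'
#' Scans a sequence for maximal perfect tandem runs of \code{motif} in any
#' of its rotations (for a trinucleotide like AGC this covers the phases
#' AGC/GCA/CAG) and returns the longest one, leftmost on ties.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param motif Repeat unit, length >= 1.
#' @return A list with elements \code{motif}, \code{start} (0-based),
#'   \code{repeat_count}, \code{span_bp}; or \code{NULL} when the motif
#'   does not occur at all.
#' @examples
#' findTandemRepeat("TTAGCAGCAGCAGCAGCGG", "AGC")  # start 2, count 5
#' @export
findTandemRepeat <- function(seq, motif = "AGC") {
    s <- .asSeqChar(seq)
    if (!nzchar(s)) stop("empty sequence")
    if (!is.character(motif) || nchar(motif) < 1L)
        stop("motif must be a non-empty string")
    runs <- .allTandemRuns(s, toupper(motif))
    if (is.null(runs)) return(NULL)
    best <- runs[order(-runs$count, runs$start), , drop = FALSE][1L, ]
    list(motif = toupper(motif), start = best$start,
         repeat_count = best$count,
         span_bp = best$count * nchar(motif))
}

#' Read the four SNP states from a reconstructed allele sequence
#'
#' Aligns a query allele to the reference allele by exact flank anchoring:
#' the only length difference permitted is inside the SSR tract (a single
#' expansion or contraction of whole repeat units). SNP offsets downstream
#' of the tract are shifted by the tract length difference before the
#' bases are read. Any other difference between query and reference -- a
#' mismatch at a non-SNP position, or a length change not attributable to
#' the tract -- is rejected as an alignment ambiguity rather than aligned
#' heuristically.
#'
#' A base that is neither the reference nor the alternative state at a SNP
#' is returned as seen and flagged in the \code{"novel"} attribute.
#'
#' @param query Query allele sequence (character or \code{DNAString}).
#' @param reference Reference allele sequence; defaults to the packaged
#'   surrogate Allele 1 ([referenceAllele()]).
#' @param snps SNP definition table as from [snpDefinitions()].
#' @param motif Repeat unit of the intragenic SSR.
#' @return Named character of bases (SNP1..SNP4), with a logical
#'   \code{"novel"} attribute marking states outside \{ref, alt\}.
#' @examples
#' ref <- referenceAllele()
#' extractSnpStates(ref$sequence)  # C G A A
#' @export
extractSnpStates <- function(query, reference = referenceAllele()$sequence,
                             snps = snpDefinitions(), motif = "AGC") {
    q <- .asSeqChar(query)
    r <- .asSeqChar(reference)
    alignErr <- function(msg)
        stop(structure(class = c("apricotMAS_alignment_error",
                                 "error", "condition"),
             list(message = msg, call = sys.call(-1L))))
    tr <- findTandemRepeat(r, motif)
    tq <- findTandemRepeat(q, motif)
    if (is.null(tr) || is.null(tq))
        alignErr("no SSR tract found in query or reference")
    if (tq$start != tr$start)
        alignErr("SSR tract position differs between query and reference")
    delta <- tq$span_bp - tr$span_bp
    if (nchar(q) - nchar(r) != delta)
        alignErr(paste0("length difference (", nchar(q) - nchar(r),
                 " bp) is not confined to the SSR tract (", delta, " bp)"))
    qc <- strsplit(q, "")[[1L]]
    rc <- strsplit(r, "")[[1L]]
    snpRef <- snps$ref_offset            # 0-based, reference coords
    mapQ <- ifelse(snpRef >= tr$start + tr$span_bp, snpRef + delta, snpRef)
    # flank identity outside tract, SNP offsets excluded
    refEnd <- tr$start + tr$span_bp
    upIdx <- seq_len(tr$start)                       # 1-based ref coords
    dnIdx <- seq(refEnd + 1L, nchar(r))
    chkUp <- setdiff(upIdx, snpRef + 1L)
    chkDn <- setdiff(dnIdx, snpRef + 1L)
    mm <- c(chkUp[rc[chkUp] != qc[chkUp]],
            chkDn[rc[chkDn] != qc[chkDn + delta]])
    if (length(mm))
        alignErr(paste0("flank mismatch at reference offset ",
                        mm[1L] - 1L, " (0-based): query is not the ",
                        "reference plus tract-confined variation"))
    states <- qc[mapQ + 1L]
    names(states) <- snps$label
    novel <- !(states == snps$ref | states == snps$alt)
    names(novel) <- snps$label
    attr(states, "novel") <- novel
    states
}

#' Assemble an SSR size and SNP states into a named allele call
#'
#' Matches the joint (SSR amplicon size, SNP1..SNP4) state exactly against
#' the four named alleles ([alleleTable()]); any other combination is
#' preserved and labelled \code{"novel"}.
#'
#' @param ssrSize Amplicon size in bp.
#' @param snpStates Character of length 4, in SNP1..SNP4 order (names,
#'   when present, are used to reorder).
#' @return An [AlleleCall-class].
#' @examples
#' assembleHaplotype(114, c("T", "T", "A", "G"))  # Allele3
#' @export
assembleHaplotype <- function(ssrSize, snpStates) {
    if (length(snpStates) != 4L)
        stop("snpStates must hold four bases (SNP1..SNP4)")
    labs <- paste0("SNP", 1:4)
    if (!is.null(names(snpStates))) {
        if (!setequal(names(snpStates), labs))
            stop("snpStates names must be SNP1..SNP4")
        snpStates <- snpStates[labs]
    } else names(snpStates) <- labs
    snpStates <- toupper(snpStates)
    tab <- alleleTable()
    hit <- tab$ssr_size == ssrSize &
        tab$SNP1 == snpStates[["SNP1"]] & tab$SNP2 == snpStates[["SNP2"]] &
        tab$SNP3 == snpStates[["SNP3"]] & tab$SNP4 == snpStates[["SNP4"]]
    name <- if (any(hit)) tab$allele[hit][1L] else "novel"
    new("AlleleCall", ssrSize = as.numeric(ssrSize),
        snpStates = snpStates, alleleName = name)
}
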