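# Surrogate locus layout for the AP2/ERF skin color gene (Col1 region).
#
# The published locus spans 22,923,854-22,925,110 on chromosome 3
# (1257 bp); the genomic sequence itself is published only as a figure,
# so the package carries a generated surrogate honouring the documented
# constraints: the Col1 primer sites, a reference amplicon of 108 bp with
# four AGC units in reading frame on the minus strand, SNP offsets at the
# genomic spacing (SNP4 shifted 1 bp to keep both non-synonymous SNPs at
# the first base of a reverse-frame codon), synonymous codon contexts at
# SNP1/SNP2 and His/Tyr-switching contexts at SNP3/SNP4.
.col1Layout <- function() {
    list(
        refLength = 1257L,
        fwdStart = 100L,                 # 0-based
        inner1 = "TCCTAGGTTACCTAGGTTACCTAA",
        tractStart = 144L,
        refRepeatCount = 4L,
        inner2 = "TTGACCTTGACCTTGACCTTGACCTTGACCT",
        motif = "AGC",
        # forward-strand codon contexts written around each SNP; "."
        # marks the SNP base itself (offsets are 0-based ref coords)
        contexts = list(
            SNP1 = list(at = 315L, before = "", after = "AG"),
            SNP2 = list(at = 591L, before = "", after = "GG"),
            SNP3 = list(at = 398L, before = "AT", after = ""),
            SNP4 = list(at = 461L, before = "AT", after = "")
        )
    )
}

# deterministic flank generation: uniform ACGT from a seed, then scrub
# AGC-phase tandem duplications and primer words so the SSR tract is the
# unique repeat and the primer sites are unique
.makeFlank <- function(n, seed, forbidden) {
    set.seed(seed)
    x <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    for (iter in 1:200) {
        hit <- NULL
        for (w in forbidden) {
            m <- regexpr(w, x, fixed = TRUE)
            if (m != -1L) { hit <- c(pos = as.integer(m), len = nchar(w)); break }
        }
        if (is.null(hit)) return(x)
        p <- hit[["pos"]] + hit[["len"]] %/% 2L  # mutate a middle base
        old <- substr(x, p, p)
        sub <- c(A = "T", C = "A", G = "T", T = "G")[[old]]
        substr(x, p, p) <- sub
    }
    stop("could not scrub flank of forbidden words; try another flank seed")
}

#' Specification of a synthetic allele sequence
#'
#' Describes one allele of the surrogate AP2/ERF locus: the AGC repeat
#' count (4 units in the 108 bp reference allele; each extra unit adds
#' 3 bp to the amplicon and one alanine to the protein) and the bases at
#' the four SNPs. The flank seed determines the random portion of the
#' locus outside the documented features; alleles built with the same
#' flank seed share their flanks exactly, as real alleles of one gene do.
#'
#' @param repeatCount Integer >= 2, number of AGC units.
#' @param snpStates Character of length 4 in SNP1..SNP4 order (named or
#'   positional); defaults to the reference (Allele 1) states C, G, A, A.
#' @param flankSeed Integer seed for the undocumented flank sequence.
#' @return A list of class \code{"alleleSpec"}.
#' @seealso [simulateAlleleSequence()], [namedAlleleSpecs()]
#' @export
alleleSpec <- function(repeatCount = 4L,
                       snpStates = c(SNP1 = "C", SNP2 = "G",
                                     SNP3 = "A", SNP4 = "A"),
                       flankSeed = 20260102L) {
    repeatCount <- as.integer(repeatCount)
    if (is.na(repeatCount) || repeatCount < 2L)
        stop("repeatCount must be an integer >= 2 ",
             "(a single unit is not a tandem repeat)")
    labs <- paste0("SNP", 1:4)
    if (length(snpStates) != 4L)
        stop("snpStates must hold four bases")
    if (!is.null(names(snpStates)) && setequal(names(snpStates), labs))
        snpStates <- snpStates[labs]
    snpStates <- toupper(as.character(snpStates))
    names(snpStates) <- labs
    if (any(!snpStates %in% c("A", "C", "G", "T")))
        stop("snpStates must be bases (ACGT)")
    structure(list(repeatCount = repeatCount, snpStates = snpStates,
                   flankSeed = as.integer(flankSeed)),
              class = "alleleSpec")
}

#' Specs of the four named alleles
#'
#' @param flankSeed Flank seed shared by the four alleles.
#' @return Named list of [alleleSpec()] objects (\code{Allele1..Allele4})
#'   whose amplicon sizes are 108, 111, 114 and 120 bp.
#' @export
namedAlleleSpecs <- function(flankSeed = 20260102L) {
    tab <- alleleTable()
    out <- lapply(seq_len(nrow(tab)), function(i)
        alleleSpec(repeatCount = 4L + (tab$ssr_size[i] - 108L) %/% 3L,
                   snpStates = c(SNP1 = tab$SNP1[i], SNP2 = tab$SNP2[i],
                                 SNP3 = tab$SNP3[i], SNP4 = tab$SNP4[i]),
                   flankSeed = flankSeed))
    names(out) <- tab$allele
    out
}

#' Generate a surrogate allele sequence of the skin color locus
#'
#' Builds the full locus sequence of one allele from its specification:
#' left flank, Col1 forward-primer site, inner flank, the AGC tract,
#' inner flank carrying the four SNP contexts, the reverse-primer site
#' and right flank. The construction is a pure function of the spec
#' (including its flank seed) and is validated before being returned:
#' both primer sites must be unique on the template, the AGC tract must
#' be the unique longest repeat run, and the SNP codon contexts must be
#' intact. A spec whose flanks collide with these features is rejected
#' with a construction error.
#'
#' @param spec An [alleleSpec()] (or an [AlleleCall-class], whose SSR size
#'   and states are converted).
#' @return List with elements \code{sequence} (character), \code{name},
#'   \code{tract_start} (0-based), \code{repeat_count},
#'   \code{snp_offsets} (0-based, named, on this allele's coordinates),
#'   \code{amplicon_size} (bp of the Col1 product), \code{primers}.
#' @examples
#' ref <- simulateAlleleSequence(alleleSpec())
#' ref$amplicon_size  # 108
#' @export
simulateAlleleSequence <- function(spec) {
    if (is(spec, "AlleleCall")) {
        nRep <- 4 + (ssrSize(spec) - 108) / 3
        if (nRep != round(nRep))
            stop("SSR size ", ssrSize(spec),
                 " cannot be rendered: off-frame repeat count")
        spec <- alleleSpec(repeatCount = nRep, snpStates = snpStates(spec))
    }
    if (!inherits(spec, "alleleSpec"))
        stop("spec must come from alleleSpec()")
    lay <- .col1Layout()
    pp <- col1Primers()
    fwd <- pp@forward
    rcRev <- .revcomp(pp@reverse)
    snps <- snpDefinitions()

    forbidden <- c("AGCAGC", "GCAGCA", "CAGCAG",
                   fwd, .revcomp(fwd), pp@reverse, rcRev)
    left <- .makeFlank(lay$fwdStart, spec$flankSeed, forbidden)
    tailRandLen <- lay$refLength -
        (lay$fwdStart + nchar(fwd) + nchar(lay$inner1) +
         3L * lay$refRepeatCount + nchar(lay$inner2) + nchar(rcRev))
    right <- .makeFlank(tailRandLen, spec$flankSeed + 1L, forbidden)

    # reference-coordinate tail: everything downstream of the tract
    tailStartRef <- lay$tractStart + 3L * lay$refRepeatCount
    tail <- paste0(lay$inner2, rcRev, right)
    writeAt <- function(s, refPos, txt) {   # refPos 0-based ref coords
        p <- refPos - tailStartRef + 1L     # 1-based in tail
        if (p < 1L || p + nchar(txt) - 1L > nchar(tail))
            stop("SNP context outside the tail segment")
        substr(s, p, p + nchar(txt) - 1L) <- txt
        s
    }
    for (i in seq_len(nrow(snps))) {
        lab <- snps$label[i]
        ctx <- lay$contexts[[lab]]
        stopifnot(ctx$at == snps$ref_offset[i])
        txt <- paste0(ctx$before, spec$snpStates[[lab]], ctx$after)
        tail <- writeAt(tail, ctx$at - nchar(ctx$before), txt)
    }

    template <- paste0(left, fwd, lay$inner1,
                       strrep(lay$motif, spec$repeatCount), tail)

    # ---- validation --------------------------------------------------
    delta <- 3L * (spec$repeatCount - lay$refRepeatCount)
    if (nchar(template) != lay$refLength + delta)
        stop("internal construction error: unexpected template length")
    if (countPattern(fwd, DNAString(template)) != 1L ||
        countPattern(rcRev, DNAString(template)) != 1L ||
        countPattern(.revcomp(fwd), DNAString(template)) != 0L ||
        countPattern(pp@reverse, DNAString(template)) != 0L)
        stop("primer site is not unique on the template; ",
             "the flank seed collides with the assay, pick another")
    runs <- .allTandemRuns(template, lay$motif)
    tractRows <- runs$start == lay$tractStart &
        runs$count == spec$repeatCount
    if (!any(tractRows))
        stop("the AGC tract is not intact on the template")
    other <- runs$count[!tractRows]
    if (length(other) && max(other) >= spec$repeatCount)
        stop("a flank repeat run matches or exceeds the SSR tract; ",
             "pick another flank seed")
    snpOffsets <- ifelse(snps$ref_offset >= tailStartRef,
                         snps$ref_offset + delta, snps$ref_offset)
    names(snpOffsets) <- snps$label
    seen <- vapply(snpOffsets, function(o)
        substr(template, o + 1L, o + 1L), character(1))
    if (!all(seen == spec$snpStates))
        stop("internal construction error: SNP states not written")

    ampliconSize <- 108L + delta
    list(sequence = template,
         name = sprintf("SSR%d_%s", ampliconSize,
                        paste(spec$snpStates, collapse = "")),
         tract_start = lay$tractStart,
         repeat_count = spec$repeatCount,
         snp_offsets = snpOffsets,
         amplicon_size = ampliconSize,
         primers = pp)
}

#' The surrogate reference allele (Allele 1)
#'
#' Allele 1 -- SSR108 with SNP states C, G, A, A -- is the reference
#' state, consistent with the yellow cultivar 'Currot' being C/C at SNP1
#' and 108/108 at Col1.
#'
#' @param flankSeed Flank seed (must match the alleles compared to it).
#' @return As [simulateAlleleSequence()].
#' @export
referenceAllele <- function(flankSeed = 20260102L) {
    simulateAlleleSequence(alleleSpec(flankSeed = flankSeed))
}

# ---- cohort simulation -------------------------------------------------

#' Configuration for a synthetic phenotyping cohort
#'
#' Defaults describe the study conditions of the cultivar panel: genotype
#' frequencies close to the 57-cultivar panel (C/C 0.35, C/T 0.55,
#' T/T 0.10 at SNP1), class-conditional hue distributions spanning the
#' printed ranges (orange ~ Normal(73, 2) degrees, yellow ~ Normal(88, 2)
#' degrees, truncated to (0, 180)), six colorimeter readings per
#' individual (two sides of three fruits) and a fixed chroma of 50 when
#' back-computing a*/b* from the drawn hue.
#'
#' @param nIndividuals Cohort size.
#' @param genotypeFrequencies Named probabilities over the marker's
#'   genotypes, summing to 1.
#' @param hueModel List with elements \code{orange} and \code{yellow},
#'   each \code{c(mean =, sd =)} in degrees.
#' @param replicates Colorimeter readings per individual.
#' @param mislabelRate Probability that an individual's hue is emitted
#'   from the other class's distribution (a phenotyping error, mirroring
#'   how field mismatches arise from ripening-stage differences).
#' @param chroma CIELAB chroma used to back-compute (a*, b*).
#' @param lightness Constant L* carried in the colorimeter table.
#' @param marker Marker rule (or name) whose prediction defines the true
#'   class of each genotype.
#' @param seed Integer seed; the simulation is a pure function of the
#'   config including this seed.
#' @return A list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nIndividuals = 57L,
                         genotypeFrequencies = c("C/C" = 0.35,
                                                 "C/T" = 0.55,
                                                 "T/T" = 0.10),
                         hueModel = list(orange = c(mean = 73, sd = 2),
                                         yellow = c(mean = 88, sd = 2)),
                         replicates = 6L,
                         mislabelRate = 0,
                         chroma = 50,
                         lightness = 70,
                         marker = "snp1",
                         seed = 1L) {
    if (nIndividuals < 1L) stop("nIndividuals must be positive")
    if (is.null(names(genotypeFrequencies)) ||
        any(genotypeFrequencies < 0) ||
        abs(sum(genotypeFrequencies) - 1) > 1e-8)
        stop("genotypeFrequencies must be named, non-negative and sum to 1")
    if (!all(c("orange", "yellow") %in% names(hueModel)))
        stop("hueModel needs 'orange' and 'yellow' components")
    for (cl in c("orange", "yellow"))
        if (hueModel[[cl]][["sd"]] <= 0)
            stop("hue sds must be positive")
    if (mislabelRate < 0 || mislabelRate > 1)
        stop("mislabelRate must lie in [0, 1]")
    if (replicates < 1L) stop("replicates must be positive")
    structure(list(nIndividuals = as.integer(nIndividuals),
                   genotypeFrequencies = genotypeFrequencies,
                   hueModel = hueModel,
                   replicates = as.integer(replicates),
                   mislabelRate = mislabelRate,
                   chroma = chroma, lightness = lightness,
                   marker = marker, seed = as.integer(seed)),
              class = "cohortConfig")
}

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.rtruncnorm <- function(n, mean, sd, lower = 0, upper = 180) {
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out <= lower | out >= upper)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] <= lower | out[bad] >= upper]
    }
    out
}

#' Simulate a genotyped and phenotyped cohort
#'
#' Per individual: a genotype is drawn from the configured frequencies;
#' its true class is the marker rule's prediction; with probability
#' \code{mislabelRate} the hue replicates are emitted from the other
#' class's distribution (phenotyping error); hue replicates are drawn
#' from the class-conditional truncated normal and converted back to
#' CIELAB (a*, b*) at fixed chroma. Reproducible: the same config (and
#' seed) yields identical output, and the caller's RNG state is left
#' untouched.
#'
#' @param config A [cohortConfig()].
#' @return List with \code{genotypes} (individual_id, marker_id, call),
#'   \code{colorimeter} (individual_id, fruit, side, L, a, b) and
#'   \code{truth} (individual_id, genotype, true_class, emitted_class,
#'   mislabeled).
#' @examples
#' sim <- simulateCohort(cohortConfig(nIndividuals = 20, seed = 7))
#' head(sim$truth)
#' @export
simulateCohort <- function(config = cohortConfig()) {
    if (!inherits(config, "cohortConfig"))
        stop("config must come from cohortConfig()")
    marker <- .resolveMarker(config$marker)
    gts <- names(config$genotypeFrequencies)
    trueClass <- vapply(gts, function(g)
        collapseClass(predictPhenotype(g, marker)), character(1))
    .withSeed(config$seed, {
        n <- config$nIndividuals
        ids <- sprintf("S%04d", seq_len(n))
        g <- sample(gts, n, replace = TRUE,
                    prob = config$genotypeFrequencies)
        tc <- trueClass[g]
        flip <- stats::runif(n) < config$mislabelRate
        emitted <- ifelse(flip, ifelse(tc == "orange", "yellow", "orange"),
                          tc)
        r <- config$replicates
        hue <- unlist(lapply(seq_len(n), function(i) {
            m <- config$hueModel[[emitted[i]]]
            .rtruncnorm(r, m[["mean"]], m[["sd"]])
        }))
        colorimeter <- data.frame(
            individual_id = rep(ids, each = r),
            fruit = rep(ceiling(seq_len(r) / 2), times = n),
            side = rep(rep_len(1:2, r), times = n),
            L = config$lightness,
            a = config$chroma * cospi(hue / 180),
            b = config$chroma * sinpi(hue / 180),
            stringsAsFactors = FALSE)
        list(
            genotypes = data.frame(individual_id = ids,
                                   marker_id = marker@markerId,
                                   call = unname(g),
                                   stringsAsFactors = FALSE),
            colorimeter = colorimeter,
            truth = data.frame(individual_id = ids,
                               genotype = unname(g),
                               true_class = unname(tc),
                               emitted_class = unname(emitted),
                               mislabeled = flip,
                               stringsAsFactors = FALSE))
    })
}
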