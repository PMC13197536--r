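#' @import methods
NULL

#' Hue-based skin color classes
#'
#' The three phenotype classes used throughout the package, in spectral
#' order from orange to yellow.
#'
#' @return Character vector \code{c("orange", "light_orange", "yellow")}.
#' @examples
#' hueClasses()
#' @export
hueClasses <- function() c("orange", "light_orange", "yellow")

#' MarkerRule: a marker definition with its genotype-to-phenotype lookup
#'
#' A \code{MarkerRule} describes one molecular marker (SNP or SSR) and the
#' rule mapping each admissible genotype to a predicted skin color class.
#' SNP rules carry an explicit genotype lookup covering all three genotypic
#' classes; SSR rules carry allele sets: a genotype is predicted yellow only
#' when both alleles belong to \code{yellowAlleles}, and orange as soon as
#' one allele belongs to \code{orangeAlleles} (orange-dominant model).
#'
#' @slot markerId Character, marker identifier (e.g. \code{"S3_22924169"}).
#' @slot markerType Either \code{"snp"} or \code{"ssr"}.
#' @slot genotypeToClass Named character; names are canonical genotypes
#'   (\code{"C/T"}), values are predicted classes (\code{"orange"} or
#'   \code{"yellow"}). Used for SNP markers.
#' @slot orangeAlleles,yellowAlleles Character allele sets (SSR fragment
#'   sizes in bp, as character). Used for SSR markers.
#' @seealso [apricotMarkers()] for the built-in rules,
#'   [predictPhenotype()], [markerEfficiency()].
#' @export
setClass("MarkerRule",
    representation(
        markerId = "character",
        markerType = "character",
        genotypeToClass = "character",
        orangeAlleles = "character",
        yellowAlleles = "character"
    ),
    prototype(
        genotypeToClass = character(),
        orangeAlleles = character(),
        yellowAlleles = character()
    )
)

setValidity("MarkerRule", function(object) {
    msg <- character()
    if (length(object@markerId) != 1L || !nzchar(object@markerId))
        msg <- c(msg, "markerId must be a single non-empty string")
    if (length(object@markerType) != 1L ||
        !object@markerType %in% c("snp", "ssr"))
        msg <- c(msg, "markerType must be 'snp' or 'ssr'")
    if (identical(object@markerType, "snp")) {
        map <- object@genotypeToClass
        if (length(map) == 0L || is.null(names(map)))
            msg <- c(msg, "snp rules need a named genotypeToClass lookup")
        else {
            if (!all(map %in% c("orange", "yellow")))
                msg <- c(msg, "predicted classes must be 'orange' or 'yellow'")
            if (length(map) < 3L)
                msg <- c(msg, "snp rules must cover all three genotypic classes")
            if (anyDuplicated(names(map)))
                msg <- c(msg, "duplicated genotype in rule table")
        }
    }
    if (identical(object@markerType, "ssr")) {
        if (length(object@orangeAlleles) == 0L ||
            length(object@yellowAlleles) == 0L)
            msg <- c(msg, "ssr rules need non-empty orange and yellow allele sets")
        if (length(intersect(object@orangeAlleles, object@yellowAlleles)) > 0L)
            msg <- c(msg, "orange and yellow allele sets must be disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' EfficiencyReport: marker classification efficiency
#'
#' Result container for [markerEfficiency()]: counts, per-class accuracies
#' over the binary (orange-group / yellow-group) collapse of the observed
#' phenotype, and the two efficiency statistics: unweighted (percent of
#' scored individuals classified correctly) and weighted (weighted mean of
#' per-class accuracies; the 0.5/0.5 weighting corrects class imbalance).
#'
#' @slot markerId Character, marker scored.
#' @slot nTotal,nScored,nCorrect Integer counts; missing and unknown
#'   genotypes are excluded from \code{nScored}.
#' @slot perClassAccuracy Named numeric, fraction correct within each
#'   observed binary class.
#' @slot unweighted,weighted Efficiencies in percent (raw, unrounded).
#' @slot weights Named numeric class weights summing to 1.
#' @slot misclassifiedIds Individuals scored but predicted wrongly.
#' @slot excludedIds Individuals excluded (missing call or genotype not in
#'   the rule table), with the reason as names.
#' @export
setClass("EfficiencyReport",
    representation(
        markerId = "character",
        nTotal = "integer",
        nScored = "integer",
        nCorrect = "integer",
        perClassAccuracy = "numeric",
        unweighted = "numeric",
        weighted = "numeric",
        weights = "numeric",
        misclassifiedIds = "character",
        excludedIds = "character"
    )
)

setValidity("EfficiencyReport", function(object) {
    msg <- character()
    if (object@nCorrect > object@nScored || object@nScored > object@nTotal)
        msg <- c(msg, "need nCorrect <= nScored <= nTotal")
    if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    ok <- c(object@unweighted, object@weighted)
    if (any(!is.na(ok) & (ok < 0 | ok > 100)))
        msg <- c(msg, "efficiencies must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' AlleleCall: a reconstructed candidate-gene haplotype
#'
#' Joint state of one gene copy: the SSR amplicon size (bp) and the bases at
#' the four intragenic SNPs (SNP1..SNP4), matched against the four named
#' alleles of the AP2/ERF skin color gene. Combinations absent from the
#' allele table are reported as \code{"novel"} with all fields preserved.
#'
#' @slot ssrSize Numeric amplicon size in bp.
#' @slot snpStates Named character of length 4 (SNP1..SNP4).
#' @slot alleleName One of \code{"Allele1".."Allele4"} or \code{"novel"}.
#' @seealso [assembleHaplotype()], [alleleTable()], [proteinVariant()].
#' @export
setClass("AlleleCall",
    representation(
        ssrSize = "numeric",
        snpStates = "character",
        alleleName = "character"
    )
)

setValidity("AlleleCall", function(object) {
    msg <- character()
    if (length(object@ssrSize) != 1L || object@ssrSize <= 0)
        msg <- c(msg, "ssrSize must be a single positive number")
    if (length(object@snpStates) != 4L)
        msg <- c(msg, "snpStates must hold exactly four bases (SNP1..SNP4)")
    if (length(msg)) msg else TRUE
})

#' ProteinVariant: a translated allele with its diagnostic features
#'
#' Protein-level summary of an [AlleleCall-class]: the translated sequence
#' (3'-5' frame 1, i.e. reverse-complement frame 1), the polyalanine tract
#' encoded by the AGC repeat, and the two variable residues determined by
#' the non-synonymous SNPs (SNP3 at position 195, SNP4 at position 146 of
#' the published numbering; G encodes histidine, A encodes tyrosine).
#'
#' @slot variantName \code{"Protein1".."Protein4"} or \code{"novel"}.
#' @slot sequence Amino-acid string (may be empty for calls that cannot be
#'   rendered as a sequence, e.g. off-frame SSR sizes).
#' @slot polyalaLength Length of the polyalanine tract in residues.
#' @slot polyalaStart 0-based index of the tract in \code{sequence}
#'   (\code{NA} when no sequence was built).
#' @slot residue146,residue195 One-letter amino acids at the two variable
#'   positions (H or Y).
#' @export
setClass("ProteinVariant",
    representation(
        variantName = "character",
        sequence = "character",
        polyalaLength = "numeric",
        polyalaStart = "numeric",
        residue146 = "character",
        residue195 = "character"
    )
)

#' PrimerPair: a PCR assay definition
#'
#' @slot markerId Character assay name.
#' @slot forward,reverse Primer sequences, 5'->3', ACGT only, >= 15 nt.
#' @slot expectedSize Published amplicon size in bp (informative).
#' @seealso [col1Primers()], [snp4Primers()], [insilicoPCR()].
#' @export
setClass("PrimerPair",
    representation(
        markerId = "character",
        forward = "character",
        reverse = "character",
        expectedSize = "numeric"
    )
)

setValidity("PrimerPair", function(object) {
    msg <- character()
    for (p in c(object@forward, object@reverse)) {
        if (nchar(p) < 15L)
            msg <- c(msg, "primers must be at least 15 nt")
        if (grepl("[^ACGT]", p))
            msg <- c(msg, "primers must be plain ACGT")
    }
    if (length(msg)) msg else TRUE
})

# ---- accessors ---------------------------------------------------------

#' @describeIn MarkerRule-class marker identifier
#' @param object a \code{MarkerRule} (or other object with a markerId)
#' @export
setGeneric("markerId", function(object) standardGeneric("markerId"))

#' @export
setMethod("markerId", "MarkerRule", function(object) object@markerId)

#' @export
setMethod("markerId", "EfficiencyReport", function(object) object@markerId)

#' @export
setMethod("markerId", "PrimerPair", function(object) object@markerId)

#' Accessors for EfficiencyReport
#'
#' @param object an [EfficiencyReport-class]
#' @return \code{unweightedEfficiency} and \code{weightedEfficiency} return
#'   percentages (raw, unrounded); \code{perClassAccuracy} a named fraction
#'   vector; \code{misclassifiedIds} the ids scored but mispredicted.
#' @name efficiency-accessors
NULL

#' @rdname efficiency-accessors
#' @export
setGeneric("unweightedEfficiency",
    function(object) standardGeneric("unweightedEfficiency"))

#' @rdname efficiency-accessors
#' @export
setMethod("unweightedEfficiency", "EfficiencyReport",
    function(object) object@unweighted)

#' @rdname efficiency-accessors
#' @export
setGeneric("weightedEfficiency",
    function(object) standardGeneric("weightedEfficiency"))

#' @rdname efficiency-accessors
#' @export
setMethod("weightedEfficiency", "EfficiencyReport",
    function(object) object@weighted)

#' @rdname efficiency-accessors
#' @export
setGeneric("perClassAccuracy",
    function(object) standardGeneric("perClassAccuracy"))

#' @rdname efficiency-accessors
#' @export
setMethod("perClassAccuracy", "EfficiencyReport",
    function(object) object@perClassAccuracy)

#' @rdname efficiency-accessors
#' @export
setGeneric("misclassifiedIds",
    function(object) standardGeneric("misclassifiedIds"))

#' @rdname efficiency-accessors
#' @export
setMethod("misclassifiedIds", "EfficiencyReport",
    function(object) object@misclassifiedIds)

#' Accessors for AlleleCall and ProteinVariant
#'
#' @param object an [AlleleCall-class] or [ProteinVariant-class]
#' @name allele-accessors
NULL

#' @rdname allele-accessors
#' @export
setGeneric("alleleName", function(object) standardGeneric("alleleName"))

#' @rdname allele-accessors
#' @export
setMethod("alleleName", "AlleleCall", function(object) object@alleleName)

#' @rdname allele-accessors
#' @export
setGeneric("snpStates", function(object) standardGeneric("snpStates"))

#' @rdname allele-accessors
#' @export
setMethod("snpStates", "AlleleCall", function(object) object@snpStates)

#' @rdname allele-accessors
#' @export
setGeneric("ssrSize", function(object) standardGeneric("ssrSize"))

#' @rdname allele-accessors
#' @export
setMethod("ssrSize", "AlleleCall", function(object) object@ssrSize)

#' @rdname allele-accessors
#' @export
setGeneric("variantName", function(object) standardGeneric("variantName"))

#' @rdname allele-accessors
#' @export
setMethod("variantName", "ProteinVariant", function(object) object@variantName)

#' @rdname allele-accessors
#' @export
setGeneric("polyalanineLength",
    function(object) standardGeneric("polyalanineLength"))

#' @rdname allele-accessors
#' @export
setMethod("polyalanineLength", "ProteinVariant",
    function(object) object@polyalaLength)

#' @rdname allele-accessors
#' @export
setGeneric("variantResidues",
    function(object) standardGeneric("variantResidues"))

#' @rdname allele-accessors
#' @export
setMethod("variantResidues", "ProteinVariant",
    function(object) c(residue146 = object@residue146,
                       residue195 = object@residue195))

# ---- show methods ------------------------------------------------------

setMethod("show", "MarkerRule", function(object) {
    cat("MarkerRule '", object@markerId, "' (", object@markerType, ")\n",
        sep = "")
    if (object@markerType == "snp") {
        for (g in names(object@genotypeToClass))
            cat("  ", g, " -> ", object@genotypeToClass[[g]], "\n", sep = "")
    } else {
        cat("  yellow alleles: ", paste(object@yellowAlleles, collapse = ", "),
            " bp\n  orange alleles: ",
            paste(object@orangeAlleles, collapse = ", "), " bp\n", sep = "")
    }
})

setMethod("show", "EfficiencyReport", function(object) {
    cat("EfficiencyReport for marker '", object@markerId, "'\n", sep = "")
    cat("  scored ", object@nScored, "/", object@nTotal,
        " individuals, ", object@nCorrect, " correct\n", sep = "")
    cat("  unweighted efficiency: ",
        formatPercent(object@unweighted), "%\n", sep = "")
    cat("  weighted efficiency:   ",
        formatPercent(object@weighted), "% (weights ",
        paste(sprintf("%s=%.2g", names(object@weights), object@weights),
              collapse = ", "), ")\n", sep = "")
    for (cl in names(object@perClassAccuracy))
        cat("  accuracy within ", cl, "-group: ",
            sprintf("%.3f", object@perClassAccuracy[[cl]]), "\n", sep = "")
    if (length(object@misclassifiedIds))
        cat("  misclassified: ",
            paste(object@misclassifiedIds, collapse = ", "), "\n", sep = "")
    if (length(object@excludedIds))
        cat("  excluded: ",
            paste(object@excludedIds, collapse = ", "), "\n", sep = "")
})

setMethod("show", "AlleleCall", function(object) {
    cat("AlleleCall: ", object@alleleName, " (SSR", object@ssrSize, ", ",
        paste(object@snpStates, collapse = "-"), ")\n", sep = "")
})

setMethod("show", "ProteinVariant", function(object) {
    cat("ProteinVariant: ", object@variantName,
        " (polyAla ", object@polyalaLength,
        ", residue146 = ", object@residue146,
        ", residue195 = ", object@residue195, ")\n", sep = "")
    if (nzchar(object@sequence))
        cat("  ", nchar(object@sequence), " aa\n", sep = "")
})

setMethod("show", "PrimerPair", function(object) {
    cat("PrimerPair '", object@markerId, "': ", object@forward, " / ",
        object@reverse, " (", object@expectedSize, " bp)\n", sep = "")
})
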