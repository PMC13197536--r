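#' Collapse the three hue classes to the binary scoring groups
#'
#' Markers predict a binary outcome (orange vs yellow), while phenotyping
#' distinguishes a transitional light-orange class. For scoring, light
#' orange is grouped with orange: the transitional class sits on the orange
#' side of the yellow boundary (h < 83), and this is the collapse under
#' which the published panel concordance (51/57) is reproduced.
#'
#' @param observed Character vector over [hueClasses()].
#' @return Character vector over \code{c("orange", "yellow")}.
#' @export
collapseClass <- function(observed) {
    bad <- setdiff(unique(observed), hueClasses())
    if (length(bad))
        stop("unknown hue class: ", paste(bad, collapse = ", "))
    ifelse(observed == "yellow", "yellow", "orange")
}

#' Score one prediction against an observed phenotype
#'
#' @param predicted Character vector of marker predictions
#'   (\code{"orange"}/\code{"yellow"}).
#' @param observed Character vector of observed classes over
#'   [hueClasses()].
#' @return Logical vector: prediction matches the collapsed observation.
#' @examples
#' scoreConcordance("orange", "light_orange")  # TRUE
#' scoreConcordance("orange", "yellow")        # FALSE
#' @export
scoreConcordance <- function(predicted, observed) {
    predicted == collapseClass(observed)
}

# round-half-up at `digits` decimals (base round() is round-half-even)
roundHalfUp <- function(x, digits = 1L) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

formatPercent <- function(x) sprintf("%.1f", roundHalfUp(x, 1L))

#' Marker classification efficiency
#'
#' Joins genotype calls with observed phenotypes, predicts the class from
#' the marker rule, and computes the two efficiency statistics: the
#' unweighted efficiency (percent correct of scored individuals) and the
#' weighted efficiency (weighted mean of per-class accuracies within each
#' observed binary group, default 0.5/0.5, correcting for class
#' imbalance). Missing calls (\code{"X/X"}) and genotypes not covered by
#' the rule are excluded from both numerator and denominator and reported
#' in the result.
#'
#' @param genotypes data.frame with columns \code{individual_id} and
#'   \code{call} (alias \code{genotype} accepted).
#' @param phenotypes data.frame with columns \code{individual_id} and
#'   \code{hue_class} (or \code{hue_mean}, classified via
#'   [classifyHue()]).
#' @param marker A [MarkerRule-class] or built-in marker name
#'   (see [apricotMarkers()]).
#' @param weights Named numeric weights over the binary groups, summing
#'   to 1. A positively weighted group with no scored member is an error:
#'   the weighted statistic is undefined there, not silently dropped.
#' @return An [EfficiencyReport-class].
#' @examples
#' fx <- apricotFixture("table1_gxc")
#' g <- data.frame(individual_id = fx$individual_id, call = fx$genotype)
#' markerEfficiency(g, fx, "snp1")
#' @export
markerEfficiency <- function(genotypes, phenotypes, marker,
                             weights = c(orange = 0.5, yellow = 0.5)) {
    marker <- .resolveMarker(marker)
    if (!is.data.frame(genotypes) || !"individual_id" %in% names(genotypes))
        stop("genotypes must be a data.frame with an individual_id column")
    callCol <- intersect(c("call", "genotype"), names(genotypes))[1L]
    if (is.na(callCol))
        stop("genotypes must have a 'call' (or 'genotype') column")
    if (!is.data.frame(phenotypes) ||
        !"individual_id" %in% names(phenotypes))
        stop("phenotypes must be a data.frame with an individual_id column")
    if (!"hue_class" %in% names(phenotypes)) {
        if (!"hue_mean" %in% names(phenotypes))
            stop("phenotypes need a hue_class or hue_mean column")
        phenotypes$hue_class <- classifyHue(phenotypes$hue_mean)
    }
    if (is.null(names(weights)) ||
        !setequal(names(weights), c("orange", "yellow")))
        stop("weights must be named over c('orange', 'yellow')")
    if (abs(sum(weights) - 1) > 1e-8)
        stop("weights must sum to 1")

    merged <- merge(genotypes[, c("individual_id", callCol)],
                    phenotypes[, c("individual_id", "hue_class")],
                    by = "individual_id", sort = FALSE)
    if (nrow(merged) == 0L)
        stop("no individual is present in both tables")

    n <- nrow(merged)
    predicted <- character(n)
    status <- character(n)
    for (i in seq_len(n)) {
        predicted[i] <- tryCatch(
            { status[i] <- "scored"
              predictPhenotype(as.character(merged[[callCol]][i]), marker) },
            apricotMAS_not_scorable = function(e) {
                status[i] <<- "missing call"; NA_character_ },
            apricotMAS_unknown_genotype = function(e) {
                status[i] <<- "unknown genotype"; NA_character_ })
    }
    scored <- status == "scored"
    if (!any(scored))
        stop("no scorable record (all calls missing or unknown)")
    obs <- collapseClass(merged$hue_class)
    ok <- scored & scoreConcordance(predicted, merged$hue_class)

    acc <- vapply(c("orange", "yellow"), function(cl) {
        inCl <- scored & obs == cl
        if (!any(inCl)) return(NA_real_)
        sum(ok[inCl]) / sum(inCl)
    }, numeric(1))
    empty <- is.na(acc) & weights[names(acc)] > 0
    if (any(empty))
        stop("weighted efficiency undefined: no scored individual in the ",
             paste(names(acc)[empty], collapse = ", "),
             " group carries positive weight")
    weighted <- 100 * sum(weights[names(acc)] * acc, na.rm = TRUE)

    excluded <- merged$individual_id[!scored]
    names(excluded) <- status[!scored]
    new("EfficiencyReport",
        markerId = marker@markerId,
        nTotal = n,
        nScored = sum(scored),
        nCorrect = sum(ok),
        perClassAccuracy = acc,
        unweighted = 100 * sum(ok) / sum(scored),
        weighted = weighted,
        weights = weights[c("orange", "yellow")],
        misclassifiedIds = as.character(merged$individual_id[scored & !ok]),
        excludedIds = excluded)
}
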