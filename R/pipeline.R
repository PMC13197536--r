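.stage <- function(stage, expr) {
    withCallingHandlers(
        tryCatch(expr, error = function(e)
            stop("[stage ", stage, "] ", conditionMessage(e),
                 call. = FALSE)),
        warning = function(w) {
            warning("[stage ", stage, "] ", conditionMessage(w),
                    call. = FALSE)
            invokeRestart("muffleWarning")
        })
}

#' Run the genotype-phenotype concordance pipeline
#'
#' Ties the stages together: load or accept phenotypes (raw colorimeter
#' readings are aggregated and classified; tables with \code{hue_mean}
#' are classified by threshold), load or accept genotype calls, resolve
#' the marker rule, and score concordance. When the phenotype table
#' carries a printed label (the packaged fixtures do), the
#' threshold-derived class is cross-checked against it and disagreements
#' are reported alongside the result instead of failing. Every exclusion
#' (missing call, genotype outside the rule table) is logged.
#'
#' @param phenotypes A fixture name (\code{"table1_gxc"},
#'   \code{"table2_cultivars"}), a path to a phenotype or colorimeter
#'   csv, or a data.frame (colorimeter readings with \code{a}/\code{b},
#'   or phenotypes with \code{hue_mean}/\code{hue_class}).
#' @param genotypes Genotype calls: data.frame with \code{individual_id}
#'   and \code{call}, a csv path, or \code{NULL} when \code{phenotypes}
#'   names a fixture (whose \code{genotype} column is then used).
#' @param marker Marker rule or built-in name (default the HRM SNP1
#'   assay; see [apricotMarkers()]).
#' @param weights Class weights for the weighted efficiency.
#' @param verbose Log exclusions and label disagreements via
#'   \code{message()}.
#' @return List with elements \code{report} ([EfficiencyReport-class]),
#'   \code{phenotypes} (the table scored), \code{genotypes}, and
#'   \code{labelDisagreements} (rows whose printed label contradicts the
#'   threshold-derived class, or \code{NULL}).
#' @examples
#' res <- runPipeline("table1_gxc", verbose = FALSE)
#' unweightedEfficiency(res$report)  # 100
#' @export
runPipeline <- function(phenotypes, genotypes = NULL, marker = "snp1",
                        weights = c(orange = 0.5, yellow = 0.5),
                        verbose = TRUE) {
    fixtureNames <- c("table1_gxc", "table2_cultivars")
    phen <- .stage("phenotypes", {
        if (is.character(phenotypes) && length(phenotypes) == 1L) {
            if (phenotypes %in% fixtureNames) apricotFixture(phenotypes)
            else readPhenotypeTable(phenotypes)
        } else if (is.data.frame(phenotypes)) phenotypes
        else stop("unsupported phenotype source")
    })
    phen <- .stage("colorimetry", {
        if (all(c("a", "b") %in% names(phen))) phenotypeTable(phen)
        else if ("hue_class" %in% names(phen)) phen
        else if ("hue_mean" %in% names(phen)) {
            phen$hue_class <- classifyHue(phen$hue_mean)
            phen
        } else stop("phenotypes carry neither colorimeter readings ",
                    "(a, b) nor hue columns")
    })
    geno <- .stage("genotypes", {
        if (is.null(genotypes)) {
            if (!"genotype" %in% names(phen))
                stop("no genotype source given and the phenotype table ",
                     "has no genotype column")
            data.frame(individual_id = phen$individual_id,
                       call = phen$genotype, stringsAsFactors = FALSE)
        } else if (is.character(genotypes) && length(genotypes) == 1L) {
            g <- readGenotypeTable(genotypes)
            names(g)[names(g) == "call"] <- "call"
            g
        } else if (is.data.frame(genotypes)) genotypes
        else stop("unsupported genotype source")
    })
    rule <- .stage("marker", .resolveMarker(marker))

    disagreements <- NULL
    if (all(c("label_agrees", "phenotype_printed") %in% names(phen)) &&
        any(!phen$label_agrees)) {
        disagreements <- phen[!phen$label_agrees, , drop = FALSE]
        if (verbose)
            message("printed label disagrees with threshold class for: ",
                    paste(disagreements$individual_id, collapse = ", "))
    }
    report <- .stage("concordance",
                     markerEfficiency(geno, phen, rule, weights = weights))
    if (verbose && length(report@excludedIds))
        message("excluded (", paste(names(report@excludedIds),
                                    collapse = "; "), "): ",
                paste(report@excludedIds, collapse = ", "))
    list(report = report, phenotypes = phen, genotypes = geno,
         labelDisagreements = disagreements)
}
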