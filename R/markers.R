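#' Construct a MarkerRule
#'
#' @param markerId Marker identifier.
#' @param markerType \code{"snp"} or \code{"ssr"}.
#' @param genotypeToClass Named character mapping canonical genotypes to
#'   predicted classes (SNP markers).
#' @param orangeAlleles,yellowAlleles Allele sets in bp (SSR markers);
#'   numeric values are accepted and stored as character.
#' @return A validated [MarkerRule-class].
#' @examples
#' MarkerRule("toy", "snp",
#'     genotypeToClass = c("A/A" = "yellow", "A/G" = "orange",
#'                         "G/G" = "orange"))
#' @export
MarkerRule <- function(markerId, markerType = c("snp", "ssr"),
                       genotypeToClass = character(),
                       orangeAlleles = character(),
                       yellowAlleles = character()) {
    markerType <- match.arg(markerType)
    new("MarkerRule",
        markerId = as.character(markerId),
        markerType = markerType,
        genotypeToClass = genotypeToClass,
        orangeAlleles = as.character(orangeAlleles),
        yellowAlleles = as.character(yellowAlleles))
}

#' Built-in skin color marker rules
#'
#' The three validated markers of the AP2/ERF skin color gene:
#' \describe{
#'   \item{snp1}{SNP S3_22924169 (C/T). C/C predicts yellow; C/T and the
#'     rarer T/T predict orange.}
#'   \item{snp4}{SNP S3_22924316 (A/G), the non-synonymous His/Tyr site.
#'     A/A predicts yellow; A/G and G/G predict orange.}
#'   \item{col1}{Intragenic AGC microsatellite (Col1). The 108 bp allele is
#'     the yellow allele; 111, 114 and 120 bp are orange alleles, acting
#'     dominantly (any orange allele predicts orange; 108/108 predicts
#'     yellow).}
#' }
#'
#' @return Named list of [MarkerRule-class] objects with elements
#'   \code{snp1}, \code{snp4}, \code{col1}.
#' @examples
#' apricotMarkers()$snp1
#' @export
apricotMarkers <- function() {
    list(
        snp1 = MarkerRule("S3_22924169", "snp",
            genotypeToClass = c("C/C" = "yellow",
                                "C/T" = "orange",
                                "T/T" = "orange")),
        snp4 = MarkerRule("S3_22924316", "snp",
            genotypeToClass = c("A/A" = "yellow",
                                "A/G" = "orange",
                                "G/G" = "orange")),
        col1 = MarkerRule("Col1", "ssr",
            orangeAlleles = c("111", "114", "120"),
            yellowAlleles = "108")
    )
}

.resolveMarker <- function(marker) {
    if (is(marker, "MarkerRule")) return(marker)
    if (is.character(marker) && length(marker) == 1L) {
        rules <- apricotMarkers()
        if (marker %in% names(rules)) return(rules[[marker]])
        hit <- vapply(rules, markerId, character(1)) == marker
        if (any(hit)) return(rules[[which(hit)[1L]]])
        stop("unknown marker id '", marker, "'")
    }
    stop("marker must be a MarkerRule or a known marker name")
}

.snpBases <- function(marker) {
    sort(unique(unlist(strsplit(names(marker@genotypeToClass), "/",
                                fixed = TRUE))))
}

#' Parse a genotype call string
#'
#' Calls are written \code{"A/B"} (two alleles separated by a slash); the
#' code \code{"X/X"} means no amplification product was detected and is
#' flagged missing rather than parsed. Alleles are canonicalized by
#' sorting, so \code{"T/C"} and \code{"C/T"} yield identical records; SSR
#' alleles (fragment sizes in bp) sort numerically.
#'
#' @param call Character scalar, e.g. \code{"C/T"}, \code{"108/114"},
#'   \code{"X/X"}.
#' @param marker A [MarkerRule-class] or built-in marker name; SNP markers
#'   reject alleles outside the marker's two bases.
#' @param individualId Optional individual identifier carried through.
#' @return A list with elements \code{individual_id}, \code{marker_id},
#'   \code{allele_1}, \code{allele_2} (canonical order), \code{missing}.
#' @examples
#' parseGenotype("T/C", "snp1")$allele_1  # "C"
#' parseGenotype("X/X", "snp1")$missing   # TRUE
#' @export
parseGenotype <- function(call, marker, individualId = NA_character_) {
    marker <- .resolveMarker(marker)
    if (!is.character(call) || length(call) != 1L || is.na(call))
        stop("call must be a single string")
    call <- trimws(call)
    parts <- strsplit(call, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || any(!nzchar(parts)))
        stop("malformed genotype call '", call, "' (expected \"A/B\")")
    rec <- list(individual_id = individualId, marker_id = marker@markerId,
                allele_1 = NA_character_, allele_2 = NA_character_,
                missing = FALSE)
    if (identical(toupper(call), "X/X")) {
        rec$missing <- TRUE
        return(rec)
    }
    if (marker@markerType == "snp") {
        parts <- toupper(parts)
        bases <- .snpBases(marker)
        bad <- setdiff(parts, bases)
        if (length(bad))
            stop("allele '", bad[1L], "' is not one of the marker's bases (",
                 paste(bases, collapse = "/"), ") for ", marker@markerId)
        parts <- sort(parts)
    } else {
        if (any(!grepl("^[0-9]+$", parts)))
            stop("SSR alleles must be fragment sizes in bp, got '",
                 call, "'")
        parts <- as.character(sort(as.integer(parts)))
    }
    rec$allele_1 <- parts[1L]
    rec$allele_2 <- parts[2L]
    rec
}

.canonicalGenotype <- function(rec) paste(rec$allele_1, rec$allele_2,
                                          sep = "/")

#' Predict the skin color class from a marker genotype
#'
#' SNP markers: lookup of the canonical genotype in the rule table. SSR
#' markers: yellow only when both alleles are yellow alleles (108/108);
#' orange as soon as one allele belongs to the orange set (orange-dominant
#' model); other configurations are not covered by the rule.
#'
#' Missing calls (\code{"X/X"}) raise a condition of class
#' \code{apricotMAS_not_scorable}; genotypes absent from the rule table
#' raise \code{apricotMAS_unknown_genotype}. [markerEfficiency()] catches
#' both and excludes the individual, reporting it.
#'
#' @param genotype A record from [parseGenotype()] or a call string.
#' @param marker A [MarkerRule-class] or built-in marker name.
#' @return \code{"orange"} or \code{"yellow"}.
#' @examples
#' predictPhenotype("C/C", "snp1")     # yellow
#' predictPhenotype("108/114", "col1") # orange
#' @export
predictPhenotype <- function(genotype, marker) {
    marker <- .resolveMarker(marker)
    if (is.character(genotype))
        genotype <- parseGenotype(genotype, marker)
    if (isTRUE(genotype$missing))
        stop(structure(class = c("apricotMAS_not_scorable",
                                 "error", "condition"),
             list(message = "missing call (X/X): not scorable",
                  call = sys.call())))
    if (marker@markerType == "snp") {
        g <- .canonicalGenotype(genotype)
        cls <- marker@genotypeToClass[g]
        if (is.na(cls))
            stop(structure(class = c("apricotMAS_unknown_genotype",
                                     "error", "condition"),
                 list(message = paste0("genotype ", g,
                      " absent from rule table of ", marker@markerId),
                      call = sys.call())))
        return(unname(cls))
    }
    al <- c(genotype$allele_1, genotype$allele_2)
    if (all(al %in% marker@yellowAlleles)) return("yellow")
    if (any(al %in% marker@orangeAlleles)) return("orange")
    stop(structure(class = c("apricotMAS_unknown_genotype",
                             "error", "condition"),
         list(message = paste0("alleles ", paste(al, collapse = "/"),
              " not covered by rule of ", marker@markerId),
              call = sys.call())))
}
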