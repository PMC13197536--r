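#' Hue angle from CIELAB chromatic coordinates
#'
#' Computes the CIELAB hue angle h (degrees) from the a* (red-green) and b*
#' (yellow-blue) coordinates. The two-argument arctangent is used and the
#' result wrapped to [0, 360), so quadrants with a* <= 0 are well defined;
#' for fruit colorimetry (a* > 0, b* > 0) results fall in (0, 90), with
#' lower values more orange and higher values more yellow.
#'
#' @param a,b Numeric vectors of CIELAB a* and b* (recycled to a common
#'   length).
#' @return Numeric vector of hue angles in degrees, in [0, 360).
#' @examples
#' hueAngle(10, 10)  # 45
#' hueAngle(3, 9)    # 71.57
#' @export
hueAngle <- function(a, b) {
    if (!is.numeric(a) || !is.numeric(b))
        stop("a and b must be numeric")
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("a and b must be finite")
    if (any(a == 0 & b == 0))
        stop("hue angle is undefined at a* = b* = 0")
    (atan2(b, a) * 180 / pi) %% 360
}

#' Classify a hue angle into the three skin color classes
#'
#' Applies the thresholds used for apricot peel ground color:
#' orange for h < 77, yellow for h > 83, light orange in between.
#' The boundary values 77 and 83 (left open by the strict inequalities)
#' are assigned to the transitional light-orange class.
#'
#' @param h Numeric vector of hue angles in degrees, in [0, 360).
#' @return Character vector over [hueClasses()].
#' @examples
#' classifyHue(c(72.3, 79.4, 85.1))
#' @export
classifyHue <- function(h) {
    if (!is.numeric(h) || any(!is.finite(h)))
        stop("h must be finite numeric")
    if (any(h < 0 | h >= 360))
        stop("h must lie in [0, 360)")
    ifelse(h < 77, "orange", ifelse(h > 83, "yellow", "light_orange"))
}

#' Collapse UPOV peel base color categories into the three hue classes
#'
#' The UPOV apricot descriptor defines seven peel base color categories.
#' For marker work these are grouped: not visible, white, yellowish and
#' yellow green count as yellow; light orange stays light orange; medium
#' and dark orange count as orange.
#'
#' @param category Character vector of UPOV category labels (snake_case:
#'   \code{"not_visible"}, \code{"white"}, \code{"yellowish"},
#'   \code{"yellow_green"}, \code{"light_orange"}, \code{"medium_orange"},
#'   \code{"dark_orange"}).
#' @return Character vector over [hueClasses()].
#' @examples
#' upovToClass(c("white", "dark_orange", "light_orange"))
#' @export
upovToClass <- function(category) {
    map <- c(
        not_visible = "yellow", white = "yellow", yellowish = "yellow",
        yellow_green = "yellow", light_orange = "light_orange",
        medium_orange = "orange", dark_orange = "orange"
    )
    bad <- setdiff(unique(category), names(map))
    if (length(bad))
        stop("unknown UPOV category: ", paste(bad, collapse = ", "))
    unname(map[category])
}

#' Aggregate replicate colorimeter readings into one phenotype record
#'
#' Hue is computed per measurement (two sides of each of three fruits in
#' the standard protocol) and then averaged; the sample (n-1) standard
#' deviation is reported, with sd defined as 0 for a single measurement.
#' The phenotype class is assigned from the mean hue.
#'
#' @param measurements data.frame with columns \code{individual_id},
#'   \code{a}, \code{b}; optional \code{fruit} and \code{side} (checked for
#'   duplicate readings when both present).
#' @return One-row data.frame with columns \code{individual_id},
#'   \code{hue_mean}, \code{hue_sd}, \code{n}, \code{hue_class}.
#' @examples
#' m <- data.frame(individual_id = "x", a = c(15, 14), b = c(42, 40))
#' aggregateReplicates(m)
#' @export
aggregateReplicates <- function(measurements) {
    if (!is.data.frame(measurements) || nrow(measurements) == 0L)
        stop("need at least one measurement")
    need <- c("individual_id", "a", "b")
    miss <- setdiff(need, names(measurements))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    ind <- unique(measurements$individual_id)
    if (length(ind) != 1L)
        stop("measurements mix individuals: ", paste(ind, collapse = ", "))
    if (all(c("fruit", "side") %in% names(measurements))) {
        key <- paste(measurements$fruit, measurements$side)
        if (anyDuplicated(key))
            stop("duplicate (fruit, side) reading for individual ", ind)
    }
    h <- hueAngle(measurements$a, measurements$b)
    hm <- mean(h)
    hs <- if (length(h) > 1L) stats::sd(h) else 0
    data.frame(
        individual_id = ind,
        hue_mean = hm,
        hue_sd = hs,
        n = length(h),
        hue_class = classifyHue(hm),
        stringsAsFactors = FALSE
    )
}

#' Phenotype table from a full colorimeter table
#'
#' Applies [aggregateReplicates()] per individual, preserving first-seen
#' individual order.
#'
#' @param measurements data.frame of colorimeter readings (columns
#'   \code{individual_id}, \code{a}, \code{b}, optionally \code{fruit},
#'   \code{side}, \code{L}).
#' @return data.frame with one row per individual (see
#'   [aggregateReplicates()]).
#' @export
phenotypeTable <- function(measurements) {
    if (!is.data.frame(measurements) || nrow(measurements) == 0L)
        stop("empty colorimeter table")
    ids <- unique(measurements$individual_id)
    out <- lapply(ids, function(i)
        aggregateReplicates(measurements[measurements$individual_id == i,
                                         , drop = FALSE]))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
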