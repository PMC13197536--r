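# strict reader: comma-separated, UTF-8, header row; numerics must use
# the dot decimal dialect, and failures name the offending row/column
.readTable <- function(path, required, numericCols = character()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss))
        stop("missing required column(s) in ", basename(path), ": ",
             paste(miss, collapse = ", "))
    for (col in intersect(numericCols, names(df))) {
        v <- trimws(df[[col]])
        ok <- grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", v)
        if (any(!ok)) {
            i <- which(!ok)[1L]
            stop("cannot parse '", v[i], "' as a number (row ", i,
                 ", column ", col, " of ", basename(path), ")")
        }
        df[[col]] <- as.numeric(v)
    }
    df
}

#' Read pipeline input tables
#'
#' Strict comma-separated UTF-8 readers with a header row. Required
#' columns are checked; unknown columns are preserved; numeric columns
#' must use the dot-decimal dialect, and a value that does not parse is a
#' structured error naming the row and column.
#'
#' \describe{
#'   \item{\code{readColorimeterTable}}{per-reading CIELAB table:
#'     \code{individual_id}, \code{fruit}, \code{side}, \code{L},
#'     \code{a}, \code{b}.}
#'   \item{\code{readGenotypeTable}}{marker calls:
#'     \code{individual_id}, \code{marker_id}, \code{call}.}
#'   \item{\code{readPhenotypeTable}}{aggregated phenotypes:
#'     \code{individual_id} plus \code{hue_mean} and/or
#'     \code{hue_class}.}
#' }
#'
#' @param path File path.
#' @return data.frame with typed columns, row order preserved.
#' @export
readColorimeterTable <- function(path) {
    .readTable(path, c("individual_id", "fruit", "side", "L", "a", "b"),
               numericCols = c("fruit", "side", "L", "a", "b"))
}

#' @rdname readColorimeterTable
#' @export
readGenotypeTable <- function(path) {
    .readTable(path, c("individual_id", "marker_id", "call"))
}

#' @rdname readColorimeterTable
#' @export
readPhenotypeTable <- function(path) {
    df <- .readTable(path, "individual_id",
                     numericCols = c("hue_mean", "hue_sd", "n"))
    if (!any(c("hue_mean", "hue_class") %in% names(df)))
        stop("phenotype table needs a hue_mean or hue_class column")
    df
}

#' Write a table in the package's delimited dialect
#'
#' Comma-separated, UTF-8, header row, no quoting, no row names -- the
#' same dialect the readers accept, so tables round-trip.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDelimited <- function(df, path) {
    if (any(vapply(df, function(x) any(grepl("[,\"\n]", as.character(x))),
                   logical(1))))
        stop("values containing commas, quotes or newlines cannot be ",
             "written unquoted")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Packaged genotype-phenotype tables
#'
#' The two published validation sets for SNP S3_22924169, transcribed
#' digit-for-digit: \code{"table1_gxc"}, 40 seedlings of the
#' 'Goldrich' x 'Currot' F1 population, and \code{"table2_cultivars"},
#' the 57-cultivar panel. Columns: \code{id}, \code{individual_id},
#' \code{ripening_date} (ISO), \code{genotype} (SNP1 call),
#' \code{hue_mean}, \code{hue_sd}, \code{phenotype_printed} (the label as
#' printed). Two derived columns are added on load: \code{hue_class}
#' (thresholds applied to \code{hue_mean} via [classifyHue()]) and
#' \code{label_agrees} (whether the printed label matches the
#' threshold-derived class; the cultivar 'Lito', printed light orange at
#' hue 75.7, is the one disagreement and is surfaced, not resolved).
#'
#' @param name \code{"table1_gxc"} or \code{"table2_cultivars"}.
#' @return data.frame (40 or 57 rows).
#' @examples
#' nrow(apricotFixture("table2_cultivars"))  # 57
#' @export
apricotFixture <- function(name = c("table1_gxc", "table2_cultivars")) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".csv"),
                        package = "apricotMAS", mustWork = TRUE)
    df <- .readTable(path,
                     c("id", "individual_id", "ripening_date", "genotype",
                       "hue_mean", "hue_sd", "phenotype_printed"),
                     numericCols = c("hue_mean", "hue_sd"))
    df$hue_class <- classifyHue(df$hue_mean)
    printed <- gsub(" ", "_", tolower(df$phenotype_printed))
    df$label_agrees <- printed == df$hue_class
    df
}
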