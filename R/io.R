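#' Packaged F2 progeny count table
#'
#' The 3 x 3 table of machine-classified F2 conidiophore phenotype counts
#' from the three crosses between homokaryotic F1 parents (AxB, BxC, AxC),
#' shipped as a delimited-text fixture.
#'
#' @return A `cross_counts` table with row totals 396, 286, 366.
#' @export
#' @examples
#' f2_counts()
f2_counts <- function() {
  read_counts(system.file("extdata", "f2_progeny_counts.csv",
                          package = "conidiomorph", mustWork = TRUE))
}

# internal: read a delimited file (comma or tab), mandatory header
read_delim_file <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(required, tolower(names(df)))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  names(df) <- tolower(names(df))
  df
}

#' Read a cross-counts table from delimited text
#'
#' Expected header `cross,wt,wrap,bulky` with one row per cross labelled
#' `AxB`, `BxC`, `AxC` (any row order; comma or tab separated).
#'
#' @param path Path to the file.
#' @return A `cross_counts` table.
#' @export
read_counts <- function(path) {
  df <- read_delim_file(path, c("cross", "wt", "wrap", "bulky"))
  if (!setequal(df$cross, cross_levels()) || nrow(df) != 3L) {
    stop(path, ": need exactly one row per cross (",
         paste(cross_levels(), collapse = ", "), "), got: ",
         paste(df$cross, collapse = ", "))
  }
  m <- as.matrix(df[match(cross_levels(), df$cross), c("wt", "wrap", "bulky")])
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(path, ": invalid count at data row ", bad[1L, 1L],
         ", column ", c("wt", "wrap", "bulky")[bad[1L, 2L]])
  }
  cross_counts(m)
}

#' Read per-colony dispersal distances from delimited text
#'
#' Expected header `strain,phenotype,replicate,distance_cm`, one row per
#' colony.
#'
#' @param path Path to the file.
#' @return Data frame with validated columns; phenotype labels checked
#'   against [phenotype_levels()].
#' @export
read_distances <- function(path) {
  df <- read_delim_file(path, c("strain", "phenotype", "replicate", "distance_cm"))
  bad <- which(!df$phenotype %in% phenotype_levels())
  if (length(bad)) {
    stop(path, ": unknown phenotype '", df$phenotype[bad[1L]],
         "' at data row ", bad[1L])
  }
  bad <- which(!is.finite(df$distance_cm) | df$distance_cm < 0)
  if (length(bad)) {
    stop(path, ": invalid distance at data row ", bad[1L])
  }
  df
}

#' Read germination plate records from delimited text
#'
#' Expected header
#' `strain,phenotype,carbon_source,concentration_pct,rep1,rep2,rep3,expected,first_day`
#' (`first_day` may be empty).
#'
#' @param path Path to the file.
#' @return Data frame of validated records with a derived `condition`
#'   column (`carbon_source` at `concentration_pct`%).
#' @export
read_germination <- function(path) {
  df <- read_delim_file(path, c("strain", "phenotype", "carbon_source",
                                "concentration_pct", "rep1", "rep2", "rep3",
                                "expected", "first_day"))
  reps <- as.matrix(df[, c("rep1", "rep2", "rep3")])
  bad <- which(!is.finite(reps) | reps < 0, arr.ind = TRUE)
  if (nrow(bad)) stop(path, ": invalid replicate count at data row ", bad[1L, 1L])
  bad <- which(!is.finite(df$expected) | df$expected <= 0)
  if (length(bad)) stop(path, ": non-positive expected count at data row ", bad[1L])
  df$condition <- paste0(df$carbon_source, " ", df$concentration_pct, "%")
  df
}

#' Read a contingency table from headered delimited text
#'
#' First column gives row labels; remaining columns are category counts.
#'
#' @param path Path to the file.
#' @return Numeric matrix with dimnames.
#' @export
read_contingency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    stop(path, ": contingency cells must be non-negative numbers")
  }
  m
}

#' Write a hierarchy report as delimited text and JSON
#'
#' Emits `<prefix>_hierarchy.csv` (chi-squared to 2 decimals, p-values to
#' 4 significant digits, with a trailing heritability line) and
#' `<prefix>_hierarchy.json` (full precision).
#'
#' @param report A `hierarchy_report` from [hierarchy_table()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_hierarchy_report <- function(report, prefix) {
  tab <- as.data.frame(report)
  h2 <- attr(report, "heritability")
  csv <- file.path(paste0(prefix, "_hierarchy.csv"))
  json <- file.path(paste0(prefix, "_hierarchy.json"))
  out <- tab
  out$chisq <- sprintf("%.2f", out$chisq)
  for (col in c("p", "p_vs")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", signif(out[[col]], 4))
  }
  out$delta_chisq <- ifelse(is.na(out$delta_chisq), "",
                            sprintf("%.2f", out$delta_chisq))
  utils::write.csv(out, csv, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(h2)) {
    cat(sprintf("heritability,%.2f,,,,,,\n", h2$h_squared),
        file = csv, append = TRUE)
  }
  payload <- list(hierarchy = tab,
                  heritability = if (is.null(h2)) NULL else unclass(h2))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
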