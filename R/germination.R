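#' Expected colony count from plating parameters
#'
#' Number of colonies expected if every plated conidium germinated:
#' suspension concentration times plated volume.
#'
#' @param concentration Conidial suspension concentration, cells per ml.
#' @param volume_plated Volume plated, ml.
#' @return Expected colony count.
#' @export
#' @examples
#' expected_colonies(1e3, 0.1)  # 100
expected_colonies <- function(concentration, volume_plated) {
  if (!is.finite(concentration) || concentration <= 0) {
    stop("concentration must be positive")
  }
  if (!is.finite(volume_plated) || volume_plated <= 0) {
    stop("volume_plated must be positive")
  }
  concentration * volume_plated
}

#' Germination rate from replicate colony counts
#'
#' Mean colony count across replicates divided by the expected colony
#' count, times 100. Because the suspension concentration is only roughly
#' calibrated the rate may exceed 100%; it is reported as-is, with a
#' warning above 120%.
#'
#' @param replicate_colony_counts Non-negative integer vector, one count
#'   per replicate plate.
#' @param expected Expected colony count (> 0).
#' @return Germination rate in percent.
#' @export
#' @examples
#' germination_rate(c(30, 45, 42), 100)  # 39
germination_rate <- function(replicate_colony_counts, expected) {
  counts <- as.numeric(replicate_colony_counts)
  if (!length(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("replicate counts must be non-negative numbers")
  }
  if (!is.finite(expected) || expected <= 0) {
    stop("expected colony count must be positive")
  }
  rate <- mean(counts) / expected * 100
  if (rate > 120) {
    warning(sprintf("germination rate %.1f%% exceeds 120%%: check the %s",
                    rate, "suspension concentration calibration"))
  }
  rate
}

#' Germination timeline table
#'
#' Pivots per-strain, per-condition first-germination days into a
#' strain x condition table and flags, per condition, any strain that
#' germinated strictly earlier than every other strain.
#'
#' @param records Data frame with columns `strain`, `condition` (e.g.
#'   carbon source + concentration), and `first_day` (integer day of first
#'   germination, `NA` allowed and excluded with a warning).
#' @return List of class `germination_timeline`: `days` (strain x
#'   condition matrix of days) and `earliest` (data frame `condition`,
#'   `strain`, the strictly earliest germinator per condition, if any).
#' @export
#' @examples
#' recs <- data.frame(strain = c("WT", "Wrap", "Bulky"),
#'                    condition = "0.1% mannose", first_day = c(4, 4, 3))
#' germination_timeline(recs)
germination_timeline <- function(records) {
  need <- c("strain", "condition", "first_day")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(records)) {
    return(structure(list(days = matrix(NA_integer_, 0, 0),
                          earliest = data.frame(condition = character(),
                                                strain = character())),
                     class = "germination_timeline"))
  }
  drop <- is.na(records$first_day)
  if (any(drop)) {
    warning(sum(drop), " record(s) without a germination day excluded")
    records <- records[!drop, , drop = FALSE]
  }
  days <- tapply(records$first_day, list(records$strain, records$condition),
                 function(v) min(v))
  earliest <- do.call(rbind, lapply(colnames(days), function(cond) {
    d <- days[, cond]
    d <- d[!is.na(d)]
    if (length(d) < 2) return(NULL)
    first <- min(d)
    winners <- names(d)[d == first]
    if (length(winners) == 1L) {
      data.frame(condition = cond, strain = winners)
    } else NULL
  }))
  if (is.null(earliest)) {
    earliest <- data.frame(condition = character(), strain = character())
  }
  structure(list(days = days, earliest = earliest),
            class = "germination_timeline")
}

#' @export
print.germination_timeline <- function(x, ...) {
  cat("First germination day (strain x condition):\n")
  print(x$days)
  if (nrow(x$earliest)) {
    cat("\nStrictly earliest germinator per condition:\n")
    print(x$earliest, row.names = FALSE)
  } else {
    cat("\nNo condition had a strictly earliest germinator.\n")
  }
  invisible(x)
}

#' Penetrance of the majority phenotype
#'
#' Fraction of a strain's classified conidiophores displaying its majority
#' architectural phenotype. Ties are broken by the fixed phenotype order
#' (WT < Wrap < Bulky) with a warning.
#'
#' @param classified_counts Named numeric vector or list mapping phenotype
#'   labels (a subset of `WT`, `Wrap`, `Bulky`) to non-negative counts.
#' @return List of class `penetrance_record`: `classified_counts`
#'   (all three phenotypes, zeros filled), `majority_phenotype`,
#'   `penetrance`, `fractions` (all three fractions, summing to 1).
#' @export
#' @examples
#' penetrance(c(WT = 8, Wrap = 1, Bulky = 1))  # WT, 0.8
penetrance <- function(classified_counts) {
  counts <- unlist(classified_counts)
  bad <- setdiff(names(counts), phenotype_levels())
  if (length(bad)) stop("unknown phenotype labels: ", paste(bad, collapse = ", "))
  full <- stats::setNames(rep(0, 3L), phenotype_levels())
  full[names(counts)] <- counts
  if (any(full < 0)) stop("counts must be non-negative")
  total <- sum(full)
  if (total <= 0) stop("total classified count must be positive")
  top <- which(full == max(full))
  if (length(top) > 1L) {
    warning("tie for majority phenotype broken by fixed order (",
            paste(names(full)[top], collapse = " = "), ")")
  }
  majority <- names(full)[top[1L]]
  structure(list(classified_counts = full,
                 majority_phenotype = majority,
                 penetrance = unname(full[majority] / total),
                 fractions = full / total),
            class = "penetrance_record")
}

#' @export
print.penetrance_record <- function(x, ...) {
  cat(sprintf("Majority phenotype %s, penetrance %.2f (n = %d)\n",
              x$majority_phenotype, x$penetrance, sum(x$classified_counts)))
  invisible(x)
}

#' Chi-squared test of independence on a contingency table
#'
#' Pearson chi-squared with expected cells `row total x column total /
#' grand total` and `df = (r - 1)(c - 1)`, without continuity correction
#' (matching the usual analysis of phenotype-by-category tables such as
#' communication group vs conidiophore phenotype). Warns when any expected
#' cell is below 5.
#'
#' @param observed Numeric matrix of non-negative counts with positive
#'   row and column margins.
#' @return List of class `association_result`: `chisq`, `df`, `p_value`,
#'   `observed`, `expected`.
#' @export
#' @examples
#' association_test(rbind(c(10, 0), c(0, 10)))  # chisq 20, df 1
association_test <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || anyNA(observed)) {
    stop("observed counts must be non-negative and complete")
  }
  if (any(rowSums(observed) <= 0) || any(colSums(observed) <= 0)) {
    stop("every row and column margin must be positive")
  }
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  if (any(expected < 5)) {
    warning("some expected cells are below 5; the chi-squared ",
            "approximation may be poor")
  }
  chisq <- pearson_chisq(observed, expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: chisq = %.4f, df = %d, P = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}
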