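#' Conidiophore phenotype labels
#'
#' The three architectural phenotypes in fixed order. Gene A underlies the
#' Wild-Type (linear chain) phenotype, gene B the Wrap phenotype, and gene C
#' the Bulky phenotype. This ordering (WT < Wrap < Bulky) is used for every
#' table row, column, and tie-break in the package.
#'
#' @return Character vector `c("WT", "Wrap", "Bulky")`.
#' @export
#' @examples
#' phenotype_levels()
phenotype_levels <- function() c("WT", "Wrap", "Bulky")

#' Cross labels in fixed order
#'
#' The three pairwise crosses between homokaryotic parents, in the fixed
#' order used by all count tables: A x B, B x C, A x C.
#'
#' @return Character vector `c("AxB", "BxC", "AxC")`.
#' @export
cross_levels <- function() c("AxB", "BxC", "AxC")

#' Model parameter names in fixed order
#'
#' Three allelic effects followed by the three pairwise epistatic
#' interactions: alpha (gene A), beta (gene B), gamma (gene C), then
#' alpha_beta, beta_gamma, alpha_gamma.
#'
#' @return Character vector of the six parameter names.
#' @export
parameter_names <- function() {
  c("alpha", "beta", "gamma", "alpha_beta", "beta_gamma", "alpha_gamma")
}

#' Construct a cross-counts table
#'
#' Builds the validated 3 x 3 table of progeny phenotype counts: one row per
#' cross (AxB, BxC, AxC) and one column per phenotype (WT, Wrap, Bulky).
#'
#' @param counts Numeric 3 x 3 matrix (or object coercible to one) of
#'   non-negative integer counts, rows = crosses, columns = phenotypes.
#' @return An object of class `cross_counts`: the integer matrix with
#'   dimnames fixed to the cross and phenotype labels.
#' @export
#' @examples
#' cross_counts(rbind(c(103, 167, 126), c(142, 86, 58), c(170, 108, 88)))
cross_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) {
    stop("`counts` must be a 3 x 3 matrix (3 crosses x 3 phenotypes), got ",
         nrow(counts), " x ", ncol(counts))
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("`counts` must be numeric with no missing values")
  }
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers")
  }
  counts <- round(counts)
  if (any(rowSums(counts) <= 0)) stop("every cross must have at least one progeny")
  dimnames(counts) <- list(cross_levels(), phenotype_levels())
  structure(counts, class = c("cross_counts", class(counts)))
}

#' @export
print.cross_counts <- function(x, ...) {
  cat("Progeny phenotype counts (rows: crosses, columns: phenotypes)\n")
  print(unclass(x))
  cat("row totals:", paste(rowSums(x), collapse = ", "), "\n")
  invisible(x)
}

# internal: validate a 6-vector of parameters, in fixed order
as_theta <- function(theta) {
  if (is.list(theta)) theta <- unlist(theta)
  if (length(theta) == 1L && theta == 0) theta <- rep(0, 6L)
  if (length(theta) != 6L) {
    stop("parameter vector must have 6 entries (",
         paste(parameter_names(), collapse = ", "), ")")
  }
  if (!all(is.finite(theta))) stop("parameters must be finite")
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), parameter_names())) {
      stop("unknown parameter names: ",
           paste(setdiff(names(theta), parameter_names()), collapse = ", "))
    }
    theta <- theta[parameter_names()]
  } else {
    names(theta) <- parameter_names()
  }
  theta
}
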