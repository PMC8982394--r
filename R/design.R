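#' Default genetic design for the three-locus linear-probability model
#'
#' Builds the per-cross design matrices that map the six-parameter vector
#' (alpha, beta, gamma, alpha_beta, beta_gamma, alpha_gamma) to deviations of
#' the three phenotype probabilities from the uniform 1/3 baseline. Each
#' cross between parents of different phenotypes involves the two dominant
#' genes of its parents and their private epistatic interaction.
#'
#' For the cross U x V (U preceding V in the gene order A < B < C), the
#' deviation of phenotype U is `theta_U + theta_UV`, of phenotype V is
#' `theta_V - theta_UV`, and of the remaining phenotype `-theta_U - theta_V`,
#' so that every column sums to zero across the three phenotypes and fitted
#' probabilities always sum to one per cross. The sign convention (the
#' interaction enters with + on the alphabetically first gene) is arbitrary
#' and documented; the stacked 9 x 6 matrix has full column rank 6, which is
#' what makes the full epistatic model saturated on a 3-cross table.
#'
#' @param matrices Optional list of three 3 x 6 matrices overriding the
#'   default construction (rows = phenotypes WT, Wrap, Bulky; columns = the
#'   six parameters). Each column must sum to zero within each matrix.
#' @return An object of class `genetic_design`: a list with elements
#'   `matrices` (named list of three 3 x 6 matrices, one per cross) and
#'   `baseline` (the uniform probability 1/3).
#' @export
#' @examples
#' d <- default_design()
#' sapply(d$matrices, function(m) max(abs(colSums(m))))  # all zero
default_design <- function(matrices = NULL) {
  pn <- parameter_names()
  ph <- phenotype_levels()
  if (is.null(matrices)) {
    # rows: WT, Wrap, Bulky; cols: alpha, beta, gamma, ab, bg, ag
    x_ab <- rbind(
      c( 1,  0, 0,  1, 0, 0),   # WT    = alpha + alpha_beta
      c( 0,  1, 0, -1, 0, 0),   # Wrap  = beta  - alpha_beta
      c(-1, -1, 0,  0, 0, 0))   # Bulky = -alpha - beta
    x_bc <- rbind(
      c(0, -1, -1, 0,  0, 0),   # WT    = -beta - gamma
      c(0,  1,  0, 0,  1, 0),   # Wrap  = beta + beta_gamma
      c(0,  0,  1, 0, -1, 0))   # Bulky = gamma - beta_gamma
    x_ac <- rbind(
      c( 1, 0,  0, 0, 0,  1),   # WT    = alpha + alpha_gamma
      c(-1, 0, -1, 0, 0,  0),   # Wrap  = -alpha - gamma
      c( 0, 0,  1, 0, 0, -1))   # Bulky = gamma - alpha_gamma
    matrices <- list(AxB = x_ab, BxC = x_bc, AxC = x_ac)
  } else {
    if (length(matrices) != 3L) stop("need exactly 3 per-cross matrices")
    names(matrices) <- cross_levels()
  }
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(3L, 6L))) stop("each design matrix must be 3 x 6")
    if (max(abs(colSums(m))) > 1e-8) {
      stop("design matrix columns must sum to zero across phenotypes")
    }
    dimnames(m) <- list(ph, pn)
    m
  })
  structure(list(matrices = matrices, baseline = 1 / 3),
            class = "genetic_design")
}

#' @export
print.genetic_design <- function(x, ...) {
  cat("Genetic design: per-cross 3 x 6 matrices, baseline probability 1/3\n")
  for (nm in names(x$matrices)) {
    cat("\nCross", nm, ":\n")
    print(x$matrices[[nm]])
  }
  invisible(x)
}

# internal: stack the three per-cross matrices into a 9 x 6 matrix
stack_design <- function(design) {
  do.call(rbind, design$matrices)
}

#' Phenotype probabilities implied by a parameter vector
#'
#' Forward model: per-cross probabilities `1/3 + X_i theta`.
#'
#' @param theta Numeric vector of the six effects (optionally named), or a
#'   single 0 for the no-effect model.
#' @param design A `genetic_design`, by default [default_design()].
#' @return 3 x 3 matrix of probabilities, rows = crosses, columns =
#'   phenotypes; each row sums to 1.
#' @export
#' @examples
#' model_probabilities(c(alpha = 0.06, beta = -0.03, gamma = 0.03,
#'                       alpha_beta = 0.03, beta_gamma = -0.03,
#'                       alpha_gamma = 0))
model_probabilities <- function(theta, design = default_design()) {
  theta <- as_theta(theta)
  p <- t(vapply(design$matrices,
                function(m) design$baseline + as.vector(m %*% theta),
                numeric(3L)))
  dimnames(p) <- list(cross_levels(), phenotype_levels())
  p
}

#' Read a design override from a key/value config file
#'
#' Parses a minimal YAML-style file giving the three per-cross matrices
#' row-major, e.g. `AxB: 1 0 0 1 0 0  0 1 0 -1 0 0  -1 -1 0 0 0 0` (18
#' numbers per cross, whitespace separated; one `cross: values` line per
#' cross). Column-sum-zero is validated by [default_design()].
#'
#' @param path Path to the config file.
#' @return A `genetic_design`.
#' @export
read_design <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mats <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed design line: ", ln)
    key <- trimws(parts[1L])
    if (!key %in% cross_levels()) stop("unknown cross label: ", key)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(parts[2L]), "[,[:space:]]+")[[1L]]))
    if (length(vals) != 18L || anyNA(vals)) {
      stop("cross ", key, ": expected 18 numbers (3 x 6 row-major)")
    }
    mats[[key]] <- matrix(vals, nrow = 3L, byrow = TRUE)
  }
  if (!setequal(names(mats), cross_levels())) {
    stop("design file must define all of: ", paste(cross_levels(), collapse = ", "))
  }
  default_design(matrices = mats[cross_levels()])
}
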