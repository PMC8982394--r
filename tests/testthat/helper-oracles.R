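# Shared fixtures and independent oracles used across the suite.

# The packaged F2 progeny counts as a plain matrix (for tests that build
# variants without touching the fixture file).
f2_counts_matrix <- function() {
  rbind(AxB = c(103, 167, 126),
        BxC = c(142, 86, 58),
        AxC = c(170, 108, 88))
}

# A second column-sum-zero, full-rank design (interaction signs flipped),
# used to assert design-independence of the environmental fit.
flipped_design <- function() {
  d <- default_design()
  default_design(matrices = lapply(d$matrices, function(m) {
    m[, 4:6] <- -m[, 4:6]
    m
  }))
}

# Random count table drawn from the forward model at a random small theta,
# so observed proportions are attainable and all probabilities interior.
random_cross_table <- function(n_per_cross = c(400, 300, 370)) {
  theta <- runif(6, -0.08, 0.08)
  simulate_cross_counts(theta, n_per_cross = n_per_cross)
}

# Independent ML oracle: derivative-free (Nelder-Mead) maximization of the
# multinomial log-likelihood over the free parameters, never touching the
# IRLS path.
nm_fit_theta <- function(counts, design = default_design(),
                         free = parameter_names()) {
  counts <- unclass(cross_counts(counts))
  xs <- lapply(design$matrices, function(m) m[, free, drop = FALSE])
  negll <- function(th) {
    total <- 0
    for (i in 1:3) {
      p <- 1 / 3 + as.vector(xs[[i]] %*% th)
      if (any(p <= 1e-9 | p >= 1 - 1e-9)) return(1e10)
      total <- total - sum(counts[i, ] * log(p))
    }
    total
  }
  th <- rep(0, length(free))
  for (pass in 1:4) {
    opt <- stats::optim(th, negll, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 50000))
    th <- opt$par
  }
  stats::setNames(th, free)
}

# Brute-force exact two-sample KS oracle: enumerate every interleaving of
# n1 x-ranks among n1 + n2 pooled ranks and count those whose EDF sup
# distance reaches d.
ks_enumeration_pvalue <- function(d, n1, n2) {
  positions <- utils::combn(n1 + n2, n1)
  hits <- 0L
  for (k in seq_len(ncol(positions))) {
    x_at <- logical(n1 + n2)
    x_at[positions[, k]] <- TRUE
    fx <- cumsum(x_at) / n1
    fy <- cumsum(!x_at) / n2
    if (max(abs(fx - fy)) >= d - 1e-9) hits <- hits + 1L
  }
  hits / ncol(positions)
}
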