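# Independent brute-force GP oracle: explicit kernel loops, dense inverse
# and log-determinant.  Deliberately shares no code with the package's
# Cholesky path.
naive_gp <- function(X, y, sf2, ls, sn2, Xstar = NULL, jitter = 0) {
  X <- rbind(X)
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- sf2 * exp(-sum((X[i, ] - X[j, ])^2) / (2 * ls^2))
  }
  Ky <- K + diag(sn2 + jitter, n)
  Kinv <- solve(Ky)
  lml <- -0.5 * drop(t(y) %*% Kinv %*% y) -
    0.5 * determinant(Ky, logarithm = TRUE)$modulus[1] -
    n / 2 * log(2 * pi)
  out <- list(lml = lml)
  if (!is.null(Xstar)) {
    Xstar <- rbind(Xstar)
    Ks <- matrix(0, n, nrow(Xstar))
    for (i in 1:n) for (j in seq_len(nrow(Xstar))) {
      Ks[i, j] <- sf2 * exp(-sum((X[i, ] - Xstar[j, ])^2) / (2 * ls^2))
    }
    out$mean <- drop(t(Ks) %*% Kinv %*% y)
  }
  out
}

# Small factorial-only design used by several tests.
mini_design <- function(n = 6, stages = "heading") {
  design_experiments(stages = stages)[seq_len(n), ]
}

# Small fully generated dataset (few treatments, strong band subsampling).
mini_dataset <- function(n_treat = 6, plants = 1, seed = 7, band_step = 50,
                         ...) {
  build_dataset(mini_design(n_treat), plants_per_treatment = plants,
                seed = seed, band_step = band_step, ...)
}
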