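# Independent brute-force distance correlation: explicit pairwise distance
# matrices, double centering by loops, dCov/dVar ratio.  Deliberately naive
# and separate from the package implementation.
dcor_bruteforce <- function(x, y) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      a[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
      b[i, j] <- sqrt(sum((y[i, ] - y[j, ])^2))
    }
  }
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
      B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
    }
  }
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  if (dcov2 <= 0) return(0)
  sqrt(dcov2 / sqrt(dvarx * dvary))
}

# sampled trajectory constructors for delayed_dd tests
make_met_traj <- function(values, channel = "avg") {
  structure(tibble::tibble(time = 0:10, channel = channel, value = values),
            source_kind = "metabolite_level")
}

make_trd_traj <- function(values) {
  stopifnot(length(values) == 25)
  structure(tibble::tibble(time = 0:24, channel = "avg", value = values),
            source_kind = "transcript_derivative")
}

# small three-condition experiment reused across expensive tests
small_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_genes = 40, n_tor_genes = 10, n_parallel_genes = 5,
        n_tfs = 10, n_hub_tfs = 4,
        metabolites = tibble::tibble(
          name = c("m_up", "m_down", "m_par", "m_unrel"),
          class = c("upstream", "downstream", "parallel", "unrelated")),
        seed = 42)
      cache <<- generate_experiment(cfg)
    }
    cache
  }
})

# a small motif assignment on the small experiment, cached
small_assignment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_synthetic()
      v <- enumerate_variants(noise_cvs = c(0.1, 0.3))
      cache <<- assign_motifs(sim$experiment, variants = v, n_random = 30,
                              seed = 42)
    }
    cache
  }
})
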