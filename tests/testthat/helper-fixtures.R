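# Fixture builders shared across test files.

rand_template <- function(q1 = 8, q2 = 128, p1 = 0.5, mask_p0 = 0,
                          seed = NULL) {
  gen <- function() {
    phase <- matrix(rbinom(q1 * q2, 1, p1), q1, q2)
    mask <- if (mask_p0 > 0) {
      matrix(rbinom(q1 * q2, 1, 1 - mask_p0), q1, q2)
    } else {
      matrix(1L, q1, q2)
    }
    iris_template(phase, mask)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# minimal local stand-in for withr::with_seed (keeps the suite
# dependency-free); restores the caller's RNG state
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# brute-force disagreeing-edge counter, independent of the package's
# vectorised implementation: explicit loops over the edge set
oracle_edge_counts <- function(x) {
  q1 <- nrow(x); q2 <- ncol(x)
  dv <- 0L; dh <- 0L
  for (i in seq_len(q1 - 1)) {
    for (j in seq_len(q2)) if (x[i, j] != x[i + 1, j]) dv <- dv + 1L
  }
  for (i in seq_len(q1)) {
    for (j in seq_len(q2)) {
      jn <- if (j == q2) 1L else j + 1L
      if (x[i, j] != x[i, jn]) dh <- dh + 1L
    }
  }
  list(dv = dv, dh = dh)
}

# partition oracle: positions of the partials are pairwise disjoint and
# cover the full lattice
expect_partition <- function(partials, shape) {
  q1 <- shape[1]
  keys <- unlist(lapply(partials, function(p) {
    p$positions[, 1] + p$positions[, 2] * q1
  }))
  expect_equal(sort(keys), 0:(prod(shape) - 1))
}
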