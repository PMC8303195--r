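test_that("unnormalized probability matches brute-force edge counts", {
  expect_equal(unnormalized_prob(matrix(1L, 3, 4)), 1)  # ground state
  set.seed(50)
  x <- matrix(sample(c(-1L, 1L), 9, replace = TRUE), 3, 3)
  expect_equal(unnormalized_prob(x, ising_params(0, 0)), 1)  # decoupled

  for (rep in 1:50) {
    x <- matrix(sample(c(-1L, 1L), 12, replace = TRUE), 3, 4)
    d <- oracle_edge_counts(x)
    expect_equal(unnormalized_prob(x, ising_params(0.2, 0.3)),
                 exp(-2 * 0.2 * d$dv - 2 * 0.3 * d$dh))
  }
})

test_that("acceptance ratio equals the full-pi ratio (500 random cases)", {
  set.seed(51)
  params <- ising_params(0.2, 0.3)
  for (rep in 1:500) {
    q1 <- sample(2:4, 1); q2 <- sample(3:6, 1)
    x <- matrix(sample(c(-1L, 1L), q1 * q2, replace = TRUE), q1, q2)
    k <- sample.int(q1 * q2, 1)
    xf <- x
    xf[k] <- -xf[k]
    expect_equal(acceptance_ratio(x, k, params),
                 unnormalized_prob(xf, params) / unnormalized_prob(x, params),
                 tolerance = 1e-12)
  }
})

test_that("acceptance ratio special cases and seed immutability", {
  x <- matrix(1L, 3, 4)
  expect_equal(acceptance_ratio(x, 5, ising_params(0, 0)), 1)
  # interior site, all 4 neighbours agree: exp(-4Jv - 4Jh)
  expect_equal(acceptance_ratio(x, 5, ising_params(0.2, 0.3)),
               exp(-4 * 0.2 - 4 * 0.3))
  s <- partial_template(c(3, 4), rbind(c(1, 1)), 1, 1)  # freezes k = 5
  expect_error(acceptance_ratio(x, 5, ising_params(), seed_map(s)),
               "immutable")
})

test_that("detailed balance holds for tested flips", {
  set.seed(52)
  params <- ising_params(0.2, 0.3)
  for (rep in 1:100) {
    x <- matrix(sample(c(-1L, 1L), 12, replace = TRUE), 3, 4)
    k <- sample.int(12, 1)
    xf <- x
    xf[k] <- -xf[k]
    lhs <- unnormalized_prob(x, params) *
      min(1, acceptance_ratio(x, k, params))
    rhs <- unnormalized_prob(xf, params) *
      min(1, acceptance_ratio(xf, k, params))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("metropolis run freezes seeds, honors snapshots and reproduces", {
  s <- partial_template(c(2, 3), rbind(c(0, 0), c(1, 2)), c(1, 0), c(1, 1))
  sm <- seed_map(s)

  runs <- metropolis_run(sm, ising_params(), 500, snapshots = c(0, 100, 500),
                         rng_seed = 7)
  expect_length(runs, 3)
  for (x in runs) {
    expect_equal(x[1, 1], 1L)   # bit 1 -> spin +1
    expect_equal(x[2, 3], -1L)  # bit 0 -> spin -1
  }
  # reproducibility
  runs2 <- metropolis_run(sm, ising_params(), 500, snapshots = c(0, 100, 500),
                          rng_seed = 7)
  expect_identical(runs, runs2)

  # fully frozen lattice: every snapshot equals the seed template
  full <- partial_template(c(2, 3), cbind(rep(0:1, each = 3), rep(0:2, 2)),
                           values = c(1, 0, 1, 0, 1, 0),
                           mask_values = rep(1, 6))
  frozen_runs <- metropolis_run(seed_map(full), ising_params(), 100,
                                snapshots = c(0, 100), rng_seed = 1)
  expect_identical(unclass(frozen_runs[[1]]), unclass(frozen_runs[[2]]))
  expect_equal(as.vector(frozen_runs[[1]]),
               2L * full$values[order(irising:::pos_key(full$positions, 2))] - 1L)

  # snapshot at 0 with a given init returns that init
  init <- matrix(c(1L, -1L, 1L, -1L, 1L, -1L), 2, 3)
  r0 <- metropolis_run(sm, ising_params(), 0, snapshots = 0, rng_seed = 1,
                       init = init)
  want <- init
  want[1, 1] <- 1L; want[2, 3] <- -1L  # seeds overwrite
  expect_equal(unclass(r0[[1]]), want, ignore_attr = TRUE)

  expect_error(metropolis_run(sm, ising_params(), 10, snapshots = c(5, 20)),
               "n_steps")
  expect_error(metropolis_run(sm, ising_params(), 10, snapshots = c(5, 5)),
               "strictly increasing")
})

test_that("exact enumeration is a proper distribution with known ratios", {
  sm_free <- seed_map(shape = c(2, 3))
  eg <- enumerate_gibbs(sm_free, ising_params(0.2, 0.3))
  expect_equal(sum(eg$prob), 1)
  expect_equal(nrow(eg$states), 2^6)

  # decoupled limit: uniform over T(s)
  eg0 <- enumerate_gibbs(sm_free, ising_params(0, 0))
  expect_equal(eg0$prob, rep(1 / 64, 64))

  # one free bit: P(+1)/P(-1) = exp(2 Jv v_agree_sum + 2 Jh h_agree_sum)
  # with all neighbours +1: v = 1 (edge to row 2), h = 2 (circular row)
  all1 <- matrix(1L, 2, 3)
  pos <- which(!matrix(FALSE, 2, 3))[-1]  # freeze all but position (1,1)
  s <- partial_template(c(2, 3),
                        univariate_position(pos, 2, 3) - 1L,
                        values = rep(1L, 5), mask_values = rep(1L, 5))
  eg1 <- enumerate_gibbs(seed_map(s), ising_params(0.2, 0.3))
  expect_equal(nrow(eg1$states), 2)
  ratio <- eg1$prob[eg1$states[, 1] == 1] / eg1$prob[eg1$states[, 1] == -1]
  expect_equal(ratio, exp(2 * 0.2 * 1 + 2 * 0.3 * 2), tolerance = 1e-12)

  big <- seed_map(shape = c(8, 128))
  expect_error(enumerate_gibbs(big), "refused")
})

test_that("long metropolis runs converge to the enumerated distribution", {
  # 2 x 3 lattice, 2 seed bits, 4 free bits: 16 reachable states
  s <- partial_template(c(2, 3), rbind(c(0, 0), c(1, 1)), c(1, 0), c(1, 1))
  sm <- seed_map(s)
  eg <- enumerate_gibbs(sm, ising_params(0.2, 0.3))
  reachable <- eg$prob > 0
  expect_equal(sum(reachable), 16)

  snaps <- metropolis_run(sm, ising_params(0.2, 0.3), 2e5,
                          snapshots = seq(10, 2e5, by = 10), rng_seed = 99)
  idx <- vapply(snaps, spin_state_index, numeric(1),
                free_positions = eg$free_positions)
  emp <- tabulate(idx, nbins = length(eg$prob)) / length(idx)
  tv <- 0.5 * sum(abs(emp - eg$prob))
  expect_lt(tv, 0.05)
})
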