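test_that("occlusion attack reproduces the leak and zero self-distance", {
  set.seed(60)
  x <- rand_template(8, 128)

  # degenerate leak: the full template
  full <- divide_block(x, c(1, 1))[[1]]
  atk_full <- occlusion_attack(full)
  expect_identical(atk_full$phase, x$phase)
  expect_identical(atk_full$mask, x$mask)

  # leaked partial of x matched against x scores exactly 0 under hd
  for (rep in 1:20) {
    p <- divide_r_dispersion(x, 4, rng_seed = rep)[[1]]
    atk <- occlusion_attack(p)
    expect_equal(sum(atk$mask), 256)
    expect_equal(hamming_distance(atk, x)$value, 0)
    # and mhd charges 0.5 for each of the 768 blanked bits
    expect_equal(modified_hamming_distance(atk, x)$value,
                 0.5 * 768 / 1024)
  }

  # leaked mask bits propagate: invalid leaked bits stay invalid
  xo <- rand_template(8, 128, mask_p0 = 0.3)
  p <- divide_r_dispersion(xo, 4, rng_seed = 1)[[1]]
  atk <- occlusion_attack(p)
  expect_equal(sum(atk$mask), sum(p$mask_values))
})

test_that("occlusion attack against a genuine variant averages 0.2 / 0.425", {
  # reduced-scale version of the replay scenario: A' differs from A by
  # independent 0.2 flips, a 256-bit partial of A' is leaked
  set.seed(61)
  n <- 300
  hd <- numeric(n); mhd <- numeric(n)
  for (i in seq_len(n)) {
    a <- rand_template(8, 128)
    a2 <- gen_genuine_variant(a, 0.2)
    p <- divide_r_dispersion(a2, 4, rng_seed = NULL)[[1]]
    atk <- occlusion_attack(p)
    hd[i] <- hamming_distance(a, atk)$value
    mhd[i] <- modified_hamming_distance(a, atk)$value
  }
  expect_equal(mean(hd), 0.2, tolerance = 0.02)
  expect_equal(mean(mhd), 0.425, tolerance = 0.02)
})

test_that("snapshot majority implements the >= 0 -> +1 tie rule", {
  m <- function(...) matrix(c(...), 2, 3)
  s1 <- m(1, 1, -1, -1, 1, -1)
  s2 <- m(1, -1, -1, 1, 1, 1)
  # tie at every position across two snapshots that disagree everywhere
  tie <- snapshot_majority(list(s1, -s1))
  expect_true(all(tie == 1))

  # L = 1: identity
  expect_equal(unclass(snapshot_majority(list(s1))), s1, ignore_attr = TRUE)

  # three snapshots: brute-force per-position vote
  s3 <- m(-1, -1, -1, 1, -1, 1)
  got <- snapshot_majority(list(s1, s2, s3))
  want <- m(0, 0, 0, 0, 0, 0)
  for (i in 1:2) for (j in 1:3) {
    tot <- s1[i, j] + s2[i, j] + s3[i, j]
    want[i, j] <- if (tot >= 0) 1 else -1
  }
  expect_equal(unclass(got), want, ignore_attr = TRUE)

  expect_error(snapshot_majority(list()), "no snapshots")
  expect_error(snapshot_majority(list(s1, matrix(1, 3, 2))), "differ")
})

test_that("reconstructions preserve the leaked seed bits", {
  set.seed(62)
  x <- rand_template(8, 128)
  p <- divide_r_dispersion(x, 8, rng_seed = 5)[[1]]
  rc1 <- p$positions + 1L

  t0 <- reconstruct_tn(p, n = 0, rng_seed = 3)
  expect_equal(t0$phase[rc1], p$values)       # n = 0: seeds + random init
  tn <- reconstruct_tn(p, n = 2000, rng_seed = 3)
  expect_equal(tn$phase[rc1], p$values)
  expect_true(all(tn$mask == 1))              # poses as a complete probe
  rn <- reconstruct_rn(p, schedule = c(100, 200, 400), rng_seed = 4)
  expect_equal(rn$phase[rc1], p$values)

  # idempotent vote: identical snapshots vote to themselves
  snap <- to_spin(tn)
  expect_equal(unclass(snapshot_majority(list(snap, snap, snap))),
               unclass(snap), ignore_attr = TRUE)
})

test_that("complementary partials are balanced, disjoint extensions", {
  set.seed(63)
  x <- rand_template(8, 128)
  zd <- divide_z_dispersion(x, 4, rng_seed = 2)
  s_zero <- zd[[1]]   # all-zero partial
  expect_true(all(s_zero$values == 0))

  cs <- complementary_partial(s_zero, rng_seed = 9)
  nI <- length(s_zero$values)
  expect_equal(nrow(cs$positions), 2 * nI)
  # all-zero seed: every extension value must be 1
  ext <- attr(cs, "extension")
  expect_equal(nrow(ext), nI)
  expect_true(all(cs$values[(nI + 1):(2 * nI)] == 1))
  # extension disjoint from I
  k1 <- cs$positions[seq_len(nI), 1] + cs$positions[seq_len(nI), 2] * 8
  k2 <- ext[, 1] + ext[, 2] * 8
  expect_length(intersect(k1, k2), 0)
  # restriction to I is s
  expect_identical(cs$positions[seq_len(nI), ], s_zero$positions)
  expect_identical(cs$values[seq_len(nI)], s_zero$values)
  # reproducible
  expect_identical(complementary_partial(s_zero, rng_seed = 9), cs)

  # counting identity: extension zeros = ceil(|union|/2) - n0
  p_mixed <- divide_r_dispersion(x, 8, rng_seed = 3)[[1]]
  cm <- complementary_partial(p_mixed, rng_seed = 1)
  n0 <- sum(p_mixed$values == 0)
  expect_equal(sum(cm$values == 0), ceiling(2 * length(p_mixed$values) / 2))
  expect_equal(sum(cm$values[-seq_len(length(p_mixed$values))] == 0),
               length(p_mixed$values) - n0)

  # no room for an extension
  big <- divide_block(x, c(1, 1))[[1]]
  expect_error(complementary_partial(big), "N/2")
})

test_that("bagged reconstruction votes over complementary reconstructions", {
  set.seed(64)
  x <- rand_template(8, 128)
  s <- divide_z_dispersion(x, 8, rng_seed = 1)[[1]]

  # k = 1 equals the single reconstruction from c_1(s)
  seeds <- irising:::derive_seeds(42, 2)
  cs <- complementary_partial(s, rng_seed = seeds[1])
  single <- reconstruct_tn(cs, n = 500, rng_seed = seeds[2])
  bag1 <- bagged_reconstruct(s, k = 1, mode = "tn", n = 500, rng_seed = 42)
  expect_identical(bag1$phase, single$phase)

  # every bag agrees with s on I, hence so does the vote
  bag <- bagged_reconstruct(s, k = 3, mode = "rn",
                            schedule = c(100, 300), rng_seed = 7)
  expect_equal(bag$phase[s$positions + 1L], s$values)
  # deterministic replay
  bag2 <- bagged_reconstruct(s, k = 3, mode = "rn",
                             schedule = c(100, 300), rng_seed = 7)
  expect_identical(bag$phase, bag2$phase)
})

test_that("attack strength grows with leak size and rn dominates tn", {
  set.seed(65)
  cfg <- population_config(8, master_seed = 77)
  pop <- gen_population(cfg)
  mean_hd <- function(m, mode) {
    vals <- vapply(seq_along(pop$subjects), function(si) {
      x <- pop$subjects[[si]][[1]]
      p <- divide_block(x, c(1, m))[[1]]
      rec <- if (mode == "tn") {
        reconstruct_tn(p, n = 5e3, rng_seed = 1000 + si)
      } else {
        reconstruct_rn(p, schedule = 500 * (1:10), rng_seed = 2000 + si)
      }
      hamming_distance(rec, x)$value
    }, numeric(1))
    mean(vals)
  }
  tn4 <- mean_hd(4, "tn"); tn16 <- mean_hd(16, "tn")
  rn4 <- mean_hd(4, "rn")
  expect_lt(tn4, tn16)  # bigger leak -> closer reconstruction
  expect_lt(rn4, tn4 + 0.02)  # majority vote at least as strong
})
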