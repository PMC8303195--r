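#' Occlusion-attack template from a leaked partial
#'
#' Builds the probe an attacker submits after stealing one partial
#' reference: the phase holds the leaked bits at the leaked positions
#' (0 elsewhere -- those bits are never compared) and the mask is valid
#' exactly at leaked positions whose leaked mask bit was valid, 0
#' everywhere else.  Against the unreplaced original and the plain
#' Hamming distance this probe scores 0 by construction; the modified
#' Hamming distance charges 0.5 for every blanked bit instead.
#'
#' @param leaked a [partial_template].
#' @return An [iris_template].
#' @export
occlusion_attack <- function(leaked) {
  stopifnot(inherits(leaked, "partial_template"))
  shape <- leaked$origin_shape
  phase <- matrix(0L, shape[1L], shape[2L])
  mask <- matrix(0L, shape[1L], shape[2L])
  rc1 <- leaked$positions + 1L
  phase[rc1] <- leaked$values
  mask[rc1] <- leaked$mask_values
  iris_template(phase, mask)
}

#' Per-position majority vote over snapshots
#'
#' The r-type intruder template: position i gets spin +1 when the sum
#' of the snapshot spins at i is >= 0 (ties resolve to +1), and -1
#' otherwise.
#'
#' @param snapshots nonempty list of equal-shape spin matrices.
#' @return A spin matrix of class `spin_view`.
#' @export
snapshot_majority <- function(snapshots) {
  if (length(snapshots) == 0L) stop("no snapshots to vote over", call. = FALSE)
  mats <- lapply(snapshots, as_spin_matrix)
  d <- dim(mats[[1L]])
  for (m in mats) {
    if (!identical(dim(m), d)) stop("snapshot shapes differ", call. = FALSE)
  }
  total <- Reduce(`+`, mats)
  v <- matrix(ifelse(total >= 0L, 1L, -1L), d[1L], d[2L])
  class(v) <- c("spin_view", class(v))
  v
}

#' Single-endpoint intruder template t^n
#'
#' Runs the seed-constrained Metropolis chain for `n` proposals from a
#' random initial state and returns the endpoint as a full template.
#' Reconstructed templates carry an all-valid mask: they pose as
#' complete probes.
#'
#' @param s the leaked [partial_template] (the seeds).
#' @param n number of Metropolis proposals (default 1e5).
#' @param params an [ising_params].
#' @param rng_seed integer seed.
#' @return An [iris_template] agreeing with `s` on its positions.
#' @export
reconstruct_tn <- function(s, n = 1e5, params = ising_params(),
                           rng_seed = NULL) {
  snaps <- metropolis_run(seed_map(s), params, n_steps = n, snapshots = n,
                          rng_seed = rng_seed)
  from_spin(snaps[[1L]])
}

#' Snapshot-majority intruder template r^n
#'
#' Runs one Metropolis trajectory, records it at the iteration counts in
#' `schedule` (default 1000, 2000, ..., 1e5), and majority-votes the
#' snapshots per position ([snapshot_majority()]).
#'
#' @param s the leaked [partial_template].
#' @param schedule strictly increasing vector of snapshot iterations.
#' @inheritParams reconstruct_tn
#' @return An [iris_template] agreeing with `s` on its positions.
#' @export
reconstruct_rn <- function(s, schedule = 1000 * (1:100),
                           params = ising_params(), rng_seed = NULL) {
  snaps <- metropolis_run(seed_map(s), params, n_steps = max(schedule),
                          snapshots = schedule, rng_seed = rng_seed)
  from_spin(snapshot_majority(snaps))
}

#' Complementary partial template c(s)
#'
#' Z-dispersion partials are value-homogeneous, which starves the Ising
#' dynamics of contrast.  c(s) extends s by a uniformly random disjoint
#' position set I' with |I'| = |I|, assigning the new values so that
#' zeros make up 50% of I (union) I' (rounded up when the union has odd
#' size).  The restriction of c(s) to I is exactly s.
#'
#' @param s a [partial_template] with |I| <= N/2.
#' @param rng_seed integer seed.
#' @return A [partial_template] on I (union) I'; its extension
#'   positions are in `attr(, "extension")` (0-based matrix).
#' @export
complementary_partial <- function(s, rng_seed = NULL) {
  stopifnot(inherits(s, "partial_template"))
  shape <- s$origin_shape
  N <- prod(shape)
  nI <- nrow(s$positions)
  if (2L * nI > N) {
    stop("no room for a disjoint extension: |I| > N/2", call. = FALSE)
  }
  q1 <- shape[1L]
  taken <- pos_key(s$positions, q1)
  avail <- setdiff(seq_len(N), taken)
  total <- 2L * nI
  target_zeros <- as.integer(ceiling(total / 2))
  n0 <- sum(s$values == 0L)
  ext_zeros <- target_zeros - n0
  if (ext_zeros < 0L || ext_zeros > nI) {
    stop(sprintf(paste0("cannot balance zeros: s has %d zeros of %d bits, ",
                        "extension of %d bits would need %d zeros"),
                 n0, nI, nI, ext_zeros), call. = FALSE)
  }
  with_rng_seed(rng_seed, {
    iprime <- sample(avail, nI)
    ext_values <- sample(c(rep(0L, ext_zeros), rep(1L, nI - ext_zeros)))
    rc1 <- univariate_position(iprime, q1, shape[2L])
    out <- partial_template(shape,
                            rbind(s$positions, rc1 - 1L),
                            c(s$values, ext_values),
                            c(s$mask_values, rep(1L, nI)))
    attr(out, "extension") <- rc1 - 1L
    out
  })
}

#' Bagged intruder templates t^{n,k} and r^{n,k}
#'
#' Draws `k` independent complementary partial templates c_1(s), ...,
#' c_k(s), reconstructs from each (endpoint `"tn"` or snapshot-majority
#' `"rn"`), and majority-votes the k reconstructions per position with
#' the same >= 0 -> +1 tie rule.  Each bag runs on a sub-seed derived
#' deterministically from `rng_seed`, so the whole attack replays
#' exactly.
#'
#' @param s the leaked [partial_template] (typically from
#'   Z-dispersion).
#' @param k number of bags (default 10).
#' @param mode `"tn"` or `"rn"`.
#' @param n proposals per endpoint reconstruction (mode `"tn"`).
#' @param schedule snapshot schedule (mode `"rn"`).
#' @param params an [ising_params].
#' @param rng_seed integer seed.
#' @return An [iris_template] agreeing with `s` on I.
#' @export
bagged_reconstruct <- function(s, k = 10L, mode = c("tn", "rn"),
                               n = 1e5, schedule = 1000 * (1:100),
                               params = ising_params(), rng_seed = NULL) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  seeds <- derive_seeds(rng_seed, 2L * k)
  recon <- lapply(seq_len(k), function(b) {
    cs <- complementary_partial(s, rng_seed = seeds[2L * b - 1L])
    t <- if (mode == "tn") {
      reconstruct_tn(cs, n = n, params = params, rng_seed = seeds[2L * b])
    } else {
      reconstruct_rn(cs, schedule = schedule, params = params,
                     rng_seed = seeds[2L * b])
    }
    to_spin(t)
  })
  from_spin(snapshot_majority(recon))
}
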