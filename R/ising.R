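#' Ising coupling parameters
#'
#' Vertical and horizontal coupling constants of the Seeded Ising
#' Model.  The defaults (0.2, 0.3) are the couplings under which real
#' iris-code channels were found to be best described; both lie in the
#' disordered phase of the anisotropic 2-D Ising model, which is what
#' keeps simulated templates near 50% ones.
#'
#' @param jv vertical coupling J_v.
#' @param jh horizontal coupling J_h.
#' @return An object of class `ising_params`.
#' @export
ising_params <- function(jv = 0.2, jh = 0.3) {
  stopifnot(is.finite(jv), is.finite(jh))
  structure(list(jv = as.numeric(jv), jh = as.numeric(jh)),
            class = "ising_params")
}

#' Seed maps: frozen bits for the Seeded Ising Model
#'
#' A seed map fixes the spins at the positions I of a partial template;
#' the remaining (free) positions evolve under the Metropolis dynamics.
#' T(s) denotes the set of spin lattices agreeing with the seeds on I.
#'
#' @param partial a [partial_template] supplying positions and bit
#'   values (converted to spins), or `NULL` for a plain, unseeded model.
#' @param shape lattice shape (q1, q2); taken from the partial when
#'   given.
#' @return An object of class `seed_map` with logical matrix `frozen`
#'   and integer matrix `values` (spins at frozen positions, `NA`
#'   elsewhere).
#' @export
seed_map <- function(partial = NULL, shape = NULL) {
  if (!is.null(partial)) {
    stopifnot(inherits(partial, "partial_template"))
    shape <- partial$origin_shape
  }
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, shape[1L] >= 1L, shape[2L] >= 3L)
  frozen <- matrix(FALSE, shape[1L], shape[2L])
  values <- matrix(NA_integer_, shape[1L], shape[2L])
  if (!is.null(partial)) {
    rc1 <- partial$positions + 1L
    frozen[rc1] <- TRUE
    values[rc1] <- 2L * partial$values - 1L
  }
  structure(list(shape = shape, frozen = frozen, values = values),
            class = "seed_map")
}

n_free <- function(seed) sum(!seed$frozen)

# Disagreeing edge counts of a spin lattice: vertical edges are
# non-circular (q2 * (q1 - 1) of them), horizontal edges wrap around
# each row (q1 * q2 of them).
edge_disagreements <- function(x) {
  x <- as_spin_matrix(x)
  q1 <- nrow(x); q2 <- ncol(x)
  dv <- if (q1 > 1L) sum(x[-q1, , drop = FALSE] != x[-1L, , drop = FALSE]) else 0L
  dh <- sum(x != x[, c(seq_len(q2)[-1L], 1L), drop = FALSE])
  list(dv = dv, dh = dh)
}

#' Unnormalised Seeded Ising probability
#'
#' \deqn{\pi(x) = \exp(-2 J_v d_x^v - 2 J_h d_x^h)}
#' where d_x^v and d_x^h count disagreeing vertical and horizontal
#' edges.  Vertical adjacency is non-circular; horizontal adjacency
#' wraps around each row.  Proportional to the Gibbs probability P(x)
#' on any state space containing x.
#'
#' @param x spin matrix over \{-1, +1\} (e.g. from [to_spin()]).
#' @param params an [ising_params].
#' @return A positive real.
#' @export
unnormalized_prob <- function(x, params = ising_params()) {
  d <- edge_disagreements(x)
  exp(-2 * params$jv * d$dv - 2 * params$jh * d$dh)
}

#' Metropolis acceptance ratio for a single-site flip
#'
#' For a proposal flipping the spin at univariate index k,
#' \deqn{\pi(x')/\pi(x) = \exp(2 J_v (d_{x,k}^v - a_{x,k}^v)
#'                            + 2 J_h (d_{x,k}^h - a_{x,k}^h))}
#' with d/a counting the disagreeing/agreeing edges incident to k.  The
#' acceptance probability is min(1, ratio).  Seed indices are immutable:
#' passing a k inside `seed`'s frozen set is an error.
#'
#' @param x spin matrix.
#' @param k 1-based univariate (column-major) index of the site.
#' @param params an [ising_params].
#' @param seed optional [seed_map]; used only to reject frozen k.
#' @return The ratio pi(x')/pi(x), a positive real.
#' @export
acceptance_ratio <- function(x, k, params = ising_params(), seed = NULL) {
  x <- as_spin_matrix(x)
  q1 <- nrow(x); q2 <- ncol(x)
  rc <- univariate_position(k, q1, q2)
  i <- rc[1L]; j <- rc[2L]
  if (!is.null(seed) && seed$frozen[i, j]) {
    stop("index ", k, " is a seed position; seed bits are immutable",
         call. = FALSE)
  }
  sv <- 0L
  if (i > 1L) sv <- sv + x[i - 1L, j]
  if (i < q1) sv <- sv + x[i + 1L, j]
  sh <- x[i, (j - 2L) %% q2 + 1L] + x[i, j %% q2 + 1L]
  # (d - a) per orientation equals -x_k * (sum of neighbour spins)
  exp(-2 * x[i, j] * (params$jv * sv + params$jh * sh))
}

#' Metropolis sampling of the Seeded Ising Model
#'
#' Runs the single-site Metropolis chain on T(s): at each iteration a
#' free (non-seed) index is drawn uniformly, the spin flip is proposed,
#' and accepted with probability min(1, pi(x')/pi(x)).  One iteration is
#' one proposal, accepted or not.  The draw order per iteration is
#' fixed -- the free index first, then the uniform u -- so trajectories
#' are bit-reproducible from `rng_seed`.
#'
#' @param seed a [seed_map] (or a [partial_template], coerced).
#' @param params an [ising_params].
#' @param n_steps total number of proposals.
#' @param snapshots strictly increasing vector of iteration counts (>= 0,
#'   <= `n_steps`) at which to record the lattice; defaults to
#'   `n_steps`.  A snapshot at 0 is the initial state.
#' @param rng_seed integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @param init `"random"` (free spins i.i.d. uniform on \{-1, +1\}) or a
#'   spin matrix / [iris_template] supplying the initial state (its
#'   entries at seed positions are overwritten by the seeds).
#' @return A named list of spin matrices (class `spin_view`), one per
#'   snapshot, names `"n<iteration>"`.
#' @export
metropolis_run <- function(seed, params = ising_params(), n_steps,
                           snapshots = n_steps, rng_seed = NULL,
                           init = "random") {
  if (inherits(seed, "partial_template")) seed <- seed_map(seed)
  stopifnot(inherits(seed, "seed_map"), inherits(params, "ising_params"))
  n_steps <- as.double(n_steps)
  stopifnot(length(n_steps) == 1L, n_steps >= 0)
  snapshots <- as.double(snapshots)
  if (length(snapshots) < 1L) stop("need at least one snapshot", call. = FALSE)
  if (is.unsorted(snapshots, strictly = TRUE)) {
    stop("snapshots must be strictly increasing", call. = FALSE)
  }
  if (any(snapshots < 0) || any(snapshots > n_steps)) {
    stop("snapshots must lie in [0, n_steps]", call. = FALSE)
  }
  with_rng_seed(rng_seed, {
    x <- init_state(seed, init)
    arr <- metropolis_chain_cpp(x, seed$frozen, params$jv, params$jh,
                                snapshots)
    out <- lapply(seq_along(snapshots), function(l) {
      v <- arr[, , l, drop = TRUE]
      dim(v) <- seed$shape
      class(v) <- c("spin_view", class(v))
      v
    })
    names(out) <- paste0("n", format(snapshots, scientific = FALSE,
                                     trim = TRUE))
    out
  })
}

init_state <- function(seed, init) {
  if (identical(init, "random")) {
    x <- matrix(sample(c(-1L, 1L), prod(seed$shape), replace = TRUE),
                seed$shape[1L], seed$shape[2L])
  } else {
    if (inherits(init, "iris_template")) init <- to_spin(init)
    x <- as_spin_matrix(init)
    if (!identical(dim(x), as.integer(seed$shape))) {
      stop("initial state shape disagrees with the seed map", call. = FALSE)
    }
  }
  x[seed$frozen] <- seed$values[seed$frozen]
  x
}

#' Exact Gibbs distribution by enumeration (small-lattice oracle)
#'
#' Enumerates every state of T(s) and returns the exact normalised
#' probabilities P(x) = pi(x)/Z.  Feasible only for small free sets
#' (refuses more than 20 free bits).  State `b` (0-based) assigns free
#' position t (in ascending univariate order) the spin +1 iff bit t of
#' `b` is set, so [spin_state_index()] maps a sampled lattice straight
#' to its row.
#'
#' @param seed a [seed_map] (or [partial_template]).
#' @param params an [ising_params].
#' @return List with `free_positions` (1-based univariate indices,
#'   ascending), `states` (2^f x f spin matrix), `prob` (normalised
#'   probabilities summing to 1), and `log_weight`.
#' @export
enumerate_gibbs <- function(seed, params = ising_params()) {
  if (inherits(seed, "partial_template")) seed <- seed_map(seed)
  stopifnot(inherits(seed, "seed_map"))
  free <- which(!seed$frozen)  # column-major univariate order
  f <- length(free)
  if (f > 20L) {
    stop("enumeration refused: ", f, " free bits (> 20) give ", 2^f,
         " states", call. = FALSE)
  }
  base <- seed$values
  base[!seed$frozen] <- 1L  # placeholder, overwritten per state
  nstates <- 2L^f
  states <- matrix(0L, nstates, max(f, 1L))
  logw <- numeric(nstates)
  for (b in seq_len(nstates) - 1L) {
    spins <- if (f > 0L) 2L * bitwAnd(bitwShiftR(b, seq_len(f) - 1L), 1L) - 1L
             else integer(0)
    x <- base
    x[free] <- spins
    d <- edge_disagreements(x)
    logw[b + 1L] <- -2 * params$jv * d$dv - 2 * params$jh * d$dh
    if (f > 0L) states[b + 1L, ] <- spins
  }
  w <- exp(logw - max(logw))
  list(free_positions = free, states = states, prob = w / sum(w),
       log_weight = logw)
}

#' @rdname enumerate_gibbs
#' @param x spin matrix whose state index (row of `states`) is wanted.
#' @param free_positions the `free_positions` vector returned by
#'   `enumerate_gibbs()`.
#' @export
spin_state_index <- function(x, free_positions) {
  x <- as_spin_matrix(x)
  bits <- (x[free_positions] + 1L) %/% 2L
  sum(bits * 2^(seq_along(free_positions) - 1L)) + 1L
}
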