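#' Synthetic template population configuration
#'
#' Describes a population of synthetic subjects.  Each subject's
#' underlying pattern is produced by the package's own seeded Ising
#' sampler (random hidden seeds, then Metropolis relaxation), so the
#' bits are spatially clustered the way real phase codes are -- which is
#' exactly the structure the reconstruction attacks exploit.  Same-
#' subject re-captures are modeled as independent per-bit flips of the
#' base pattern at `genuine_flip_rate`, placing genuine scores around
#' that rate and impostor scores near 0.5.
#'
#' @param n_subjects number of subjects.
#' @param templates_per_subject captures per subject (>= 2 enables the
#'   leaked-template-replaced scenario).
#' @param shape lattice shape, default c(8, 128).
#' @param params [ising_params] used for pattern generation.
#' @param genuine_flip_rate per-bit flip probability between captures of
#'   one subject (default 0.2).
#' @param occlusion_fraction expected invalid-mask fraction (default 0).
#' @param seed_fraction fraction of positions used as hidden pattern
#'   seeds (default 1/8).
#' @param sweeps Metropolis sweeps (multiples of q1*q2 proposals) of
#'   pattern relaxation (default 30).
#' @param master_seed integer master RNG seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_subjects, templates_per_subject = 2L,
                              shape = c(8L, 128L), params = ising_params(),
                              genuine_flip_rate = 0.2,
                              occlusion_fraction = 0,
                              seed_fraction = 1 / 8, sweeps = 30L,
                              master_seed = 1L) {
  stopifnot(n_subjects >= 1L, templates_per_subject >= 1L,
            genuine_flip_rate >= 0, genuine_flip_rate <= 0.5,
            occlusion_fraction >= 0, occlusion_fraction < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 templates_per_subject = as.integer(templates_per_subject),
                 shape = as.integer(shape), params = params,
                 genuine_flip_rate = genuine_flip_rate,
                 occlusion_fraction = occlusion_fraction,
                 seed_fraction = seed_fraction, sweeps = as.integer(sweeps),
                 master_seed = as.integer(master_seed)),
            class = "population_config")
}

# deterministic per-(master, stream, id) seed, valid 32-bit
scalar_seed <- function(master, stream, id) {
  s <- as.double(master %% 2147483647L)
  for (v in c(stream, id)) {
    s <- (s * 48271 + as.double(v) * 16807 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Generate one subject's base template
#'
#' Samples a small hidden seed set (i.i.d. fair bits at
#' `seed_fraction` of the positions), then relaxes the free bits with
#' the Metropolis sampler for `sweeps * q1 * q2` proposals.  At the
#' default couplings the lattice is disordered, so the pattern stays
#' near 50% ones while acquiring local spatial clustering.
#' Deterministic per (master_seed, subject_id).
#'
#' @param config a [population_config].
#' @param subject_id positive integer.
#' @return An [iris_template] (all-valid mask unless
#'   `occlusion_fraction > 0`).
#' @export
gen_subject_template <- function(config, subject_id) {
  stopifnot(inherits(config, "population_config"))
  shape <- config$shape
  N <- prod(shape)
  rs <- scalar_seed(config$master_seed, 1L, subject_id)
  with_rng_seed(rs, {
    n_seeds <- max(1L, round(config$seed_fraction * N))
    idx <- sample.int(N, n_seeds)
    values <- sample(c(0L, 1L), n_seeds, replace = TRUE)
    rc1 <- univariate_position(idx, shape[1L], shape[2L])
    s <- partial_template(shape, rc1 - 1L, values, rep(1L, n_seeds))
    n <- config$sweeps * N
    snap <- metropolis_run(seed_map(s), config$params, n_steps = n,
                           snapshots = n)
    mask <- if (config$occlusion_fraction > 0) {
      gen_occlusion_mask(shape, config$occlusion_fraction,
                         rng_seed = NULL)
    } else NULL
    from_spin(snap[[1L]], mask)
  })
}

#' Generate a genuine (same-subject) variant
#'
#' Flips each phase bit independently with probability `flip_rate`,
#' emulating re-capture noise; regenerates the occlusion mask when
#' `occlusion_fraction > 0` in `config` (pass via `mask_fraction`).
#'
#' @param base an [iris_template].
#' @param flip_rate per-bit flip probability.
#' @param rng_seed integer seed.
#' @param mask_fraction expected invalid fraction of a freshly drawn
#'   mask; 0 keeps the base mask.
#' @return An [iris_template].
#' @export
gen_genuine_variant <- function(base, flip_rate = 0.2, rng_seed = NULL,
                                mask_fraction = 0) {
  stopifnot(inherits(base, "iris_template"), flip_rate >= 0, flip_rate <= 1)
  with_rng_seed(rng_seed, {
    flips <- matrix(runif(length(base$phase)) < flip_rate,
                    nrow(base$phase), ncol(base$phase))
    phase <- ifelse(flips, 1L - base$phase, base$phase)
    mask <- if (mask_fraction > 0) {
      gen_occlusion_mask(dim(base$phase), mask_fraction, rng_seed = NULL)
    } else base$mask
    iris_template(phase, mask)
  })
}

#' Generate an occlusion mask
#'
#' Emulates eyelid/eyelash-style occlusion as a contiguous band (a
#' rectangle of top rows spanning a circular column window, holding
#' about half the invalid budget) plus i.i.d. speckle over the rest.
#' The expected invalid fraction is `fraction`.
#'
#' @param shape (q1, q2).
#' @param fraction expected invalid fraction in \[0, 1).
#' @param rng_seed integer seed.
#' @return A binary matrix (1 = valid).
#' @export
gen_occlusion_mask <- function(shape, fraction, rng_seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(fraction >= 0, fraction < 1)
  q1 <- shape[1L]; q2 <- shape[2L]
  N <- q1 * q2
  if (fraction == 0) return(matrix(1L, q1, q2))
  with_rng_seed(rng_seed, {
    mask <- matrix(1L, q1, q2)
    band_budget <- fraction * N / 2
    band_rows <- max(1L, min(q1, round(sqrt(band_budget * q1 / q2))))
    band_cols <- max(1L, min(q2, round(band_budget / band_rows)))
    start <- sample.int(q2, 1L)
    cols <- ((start - 1L + seq_len(band_cols) - 1L) %% q2) + 1L
    mask[seq_len(band_rows), cols] <- 0L
    remaining <- sum(mask == 1L)
    speckle_p <- max(0, (fraction * N - (N - remaining)) / remaining)
    hit <- runif(N) < speckle_p & mask == 1L
    mask[hit] <- 0L
    mask
  })
}

#' Generate a whole synthetic population
#'
#' For each subject: one base template
#' ([gen_subject_template()]) and `templates_per_subject - 1` genuine
#' variants ([gen_genuine_variant()]).  Fully deterministic given the
#' config's `master_seed`.
#'
#' @param config a [population_config].
#' @return An object of class `template_population`: list with
#'   `subjects` (list of lists of [iris_template]s) and `config`.
#' @export
gen_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(sid) {
    base <- gen_subject_template(config, sid)
    variants <- lapply(seq_len(config$templates_per_subject - 1L),
                       function(v) {
      gen_genuine_variant(base, config$genuine_flip_rate,
                          rng_seed = scalar_seed(config$master_seed, 2L,
                                                 sid * 1000L + v),
                          mask_fraction = config$occlusion_fraction)
    })
    c(list(base), variants)
  })
  structure(list(subjects = subjects, config = config),
            class = "template_population")
}

#' @export
print.template_population <- function(x, ...) {
  cat(sprintf("<template_population: %d subjects x %d templates (%d x %d)>\n",
              length(x$subjects), length(x$subjects[[1L]]),
              x$config$shape[1L], x$config$shape[2L]))
  invisible(x)
}
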