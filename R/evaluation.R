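#' Empirical match rate
#'
#' m(d) = |\{i : d_i <= d\}| / M -- the empirical CDF of a score
#' collection at threshold d (inclusive comparison).
#'
#' @param scores numeric vector of dissimilarity scores in \[0, 1\].
#' @param d threshold (vectorised).
#' @return Match rate(s) in \[0, 1\].
#' @export
match_rate <- function(scores, d) {
  if (length(scores) == 0L) stop("empty score set", call. = FALSE)
  vapply(d, function(th) mean(scores <= th), numeric(1L))
}

#' Intruder Match Rate
#'
#' The match rate of a collection of intruder distance scores: the
#' fraction of intruder comparisons that would be accepted at threshold
#' d.  When the intruder is the snapshot-majority attack (r^n or
#' r^{n,k}) this quantity is the scheme's *risk of leakage*.
#'
#' @inheritParams match_rate
#' @export
imr <- function(scores, d) match_rate(scores, d)

#' FMR, FNMR and EER from genuine/impostor scores
#'
#' FMR(d) is the impostor match rate; FNMR(d) = 1 - genuine match rate;
#' both use the shared [match_rate()] functional.  The EER is where the
#' two empirical curves cross, located by linear interpolation on a
#' threshold grid (default spacing 1e-3).
#'
#' @param genuine,impostor numeric score vectors (same metric).
#' @param thresholds evaluation grid.
#' @return List with `table` (data frame: threshold, fmr, fnmr) and
#'   `eer`.
#' @export
fmr_fnmr_eer <- function(genuine, impostor,
                         thresholds = seq(0, 1, by = 1e-3)) {
  stopifnot(length(genuine) >= 1L, length(impostor) >= 1L)
  fmr <- match_rate(impostor, thresholds)
  fnmr <- 1 - match_rate(genuine, thresholds)
  diff <- fnmr - fmr  # non-increasing in d
  eer <- if (diff[1L] <= 0) {
    (fmr[1L] + fnmr[1L]) / 2
  } else if (diff[length(diff)] > 0) {
    (fmr[length(diff)] + fnmr[length(diff)]) / 2
  } else {
    i <- which(diff <= 0)[1L]  # crossing between i-1 and i
    w <- diff[i - 1L] / (diff[i - 1L] - diff[i])
    f1 <- fmr[i - 1L] + w * (fmr[i] - fmr[i - 1L])
    f2 <- fnmr[i - 1L] + w * (fnmr[i] - fnmr[i - 1L])
    (f1 + f2) / 2
  }
  list(table = data.frame(threshold = thresholds, fmr = fmr, fnmr = fnmr),
       eer = eer)
}

#' Leakage-experiment configuration
#'
#' Settings for [run_leakage_experiment()]: which division schemes and
#' partial-template sizes to leak, which attacks to mount, the
#' comparison scenario, and the sampler budget.  Defaults reflect the
#' package's reduced-scale experiment: n = 1e4 endpoint proposals,
#' snapshot schedule 1e3 * (1..10), k = 5 bags, 3 intruders per
#' (subject, scheme, size).
#'
#' @param schemes subset of c("block", "r_dispersion", "z_dispersion").
#' @param sizes numbers of partial templates m (4, 8, 16 give 1/4, 1/8,
#'   1/16 partial sizes).
#' @param attacks subset of c("tn", "rn", "tn_k", "rn_k", "occlusion");
#'   the bagged attacks run only under Z-dispersion.
#' @param scenario `"not_replaced"` (compare intruders against the
#'   leaked original) or `"replaced"` (against another capture of the
#'   same subject).
#' @param thresholds numeric vector of acceptance thresholds (defaults
#'   0.4 and 0.431, the equivalent operating points of the plain and
#'   modified metrics).
#' @param n_intruders intruder templates per (subject, scheme, size).
#' @param tn_steps Metropolis proposals for endpoint reconstructions.
#' @param rn_schedule snapshot schedule for majority reconstructions.
#' @param k_bags bags for the bagged attacks.
#' @param params an [ising_params].
#' @param rng_seed master seed for the experiment.
#' @return An object of class `leakage_config`.
#' @export
leakage_config <- function(schemes = c("block", "r_dispersion", "z_dispersion"),
                           sizes = c(4L, 8L, 16L),
                           attacks = c("tn", "rn", "occlusion"),
                           scenario = c("not_replaced", "replaced"),
                           thresholds = c(0.4, 0.431),
                           n_intruders = 3L,
                           tn_steps = 1e4,
                           rn_schedule = 1000 * (1:10),
                           k_bags = 5L,
                           params = ising_params(),
                           rng_seed = 1L) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  attacks <- match.arg(attacks,
                       c("tn", "rn", "tn_k", "rn_k", "occlusion"),
                       several.ok = TRUE)
  scenario <- match.arg(scenario)
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  structure(list(schemes = schemes, sizes = as.integer(sizes),
                 attacks = attacks, scenario = scenario,
                 thresholds = thresholds,
                 n_intruders = as.integer(n_intruders),
                 tn_steps = tn_steps, rn_schedule = rn_schedule,
                 k_bags = as.integer(k_bags), params = params,
                 rng_seed = as.integer(rng_seed)),
            class = "leakage_config")
}

# default block grids: column bands, respecting the row-circular
# topology used by rotation
block_grid_for <- function(m, shape) {
  if (shape[2L] %% m == 0L) c(1L, m)
  else stop("no default block grid for m = ", m, call. = FALSE)
}

divide_by_scheme <- function(t, scheme, m, rng_seed) {
  switch(scheme,
         block = divide_block(t, block_grid_for(m, template_shape(t))),
         r_dispersion = divide_r_dispersion(t, m, rng_seed),
         z_dispersion = divide_z_dispersion(t, m, rng_seed),
         stop("unknown scheme ", scheme, call. = FALSE))
}

#' Run a leaked-partial-template attack experiment
#'
#' For every subject in the population: divide its base template by
#' each configured scheme and size, leak one partial (uniformly
#' chosen), mount the configured attacks, and score each intruder
#' template against the target -- the original base template
#' (`"not_replaced"`) or the subject's second capture (`"replaced"`) --
#' under both the plain and the modified Hamming distance.  Under
#' Z-dispersion the plain tn/rn attacks reconstruct from a fresh
#' complementary partial c(s) per intruder; the bagged attacks (tn_k,
#' rn_k) run only under Z-dispersion.  Fully deterministic given the
#' config's `rng_seed`.
#'
#' @param config a [leakage_config].
#' @param population a `template_population` (see [gen_population()]);
#'   the replaced scenario needs at least 2 templates per subject.
#' @return List with `table` -- data frame (scheme, attack, size,
#'   metric, threshold, imr, n_comparisons) -- and `scores` -- data
#'   frame of raw per-comparison scores (scheme, attack, size, metric,
#'   subject, score).
#' @export
run_leakage_experiment <- function(config, population) {
  stopifnot(inherits(config, "leakage_config"),
            inherits(population, "template_population"))
  if (config$scenario == "replaced" &&
      length(population$subjects[[1L]]) < 2L) {
    stop("replaced scenario needs >= 2 templates per subject", call. = FALSE)
  }
  n_sub <- length(population$subjects)
  cells <- expand.grid(scheme = config$schemes, size = config$sizes,
                       attack = config$attacks, stringsAsFactors = FALSE)
  keep <- !(cells$attack %in% c("tn_k", "rn_k") &
              cells$scheme != "z_dispersion")
  cells <- cells[keep, , drop = FALSE]

  score_rows <- vector("list", 0L)
  seeds <- matrix(derive_seeds(config$rng_seed, n_sub * nrow(cells)),
                  nrow = n_sub)
  for (ci in seq_len(nrow(cells))) {
    scheme <- cells$scheme[ci]; m <- cells$size[ci]; attack <- cells$attack[ci]
    for (si in seq_len(n_sub)) {
      tmpl <- population$subjects[[si]]
      x <- tmpl[[1L]]
      target <- if (config$scenario == "not_replaced") x else tmpl[[2L]]
      sub_seeds <- derive_seeds(seeds[si, ci], 2L + 2L * config$n_intruders)
      partials <- divide_by_scheme(x, scheme, m, sub_seeds[1L])
      leak <- partials[[with_rng_seed(sub_seeds[2L],
                                      sample.int(length(partials), 1L))]]
      intruders <- build_intruders(leak, scheme, attack, config,
                                   sub_seeds[-(1:2)])
      for (it in intruders) {
        hd <- tryCatch(hamming_distance(it, target)$value,
                       error = function(e) NA_real_)
        mhd <- modified_hamming_distance(it, target)$value
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          scheme = scheme, attack = attack, size = m,
          metric = c("hd", "mhd"), subject = si, score = c(hd, mhd))
      }
    }
  }
  scores <- do.call(rbind, score_rows)
  tab <- imr_table(scores, config$thresholds)
  list(table = tab, scores = scores)
}

build_intruders <- function(leak, scheme, attack, config, seeds) {
  n_int <- if (attack == "occlusion") 1L else config$n_intruders
  lapply(seq_len(n_int), function(i) {
    s1 <- seeds[2L * i - 1L]; s2 <- seeds[2L * i]
    switch(attack,
      occlusion = occlusion_attack(leak),
      tn = {
        s_eff <- if (scheme == "z_dispersion") {
          complementary_partial(leak, rng_seed = s1)
        } else leak
        reconstruct_tn(s_eff, n = config$tn_steps, params = config$params,
                       rng_seed = s2)
      },
      rn = {
        s_eff <- if (scheme == "z_dispersion") {
          complementary_partial(leak, rng_seed = s1)
        } else leak
        reconstruct_rn(s_eff, schedule = config$rn_schedule,
                       params = config$params, rng_seed = s2)
      },
      tn_k = bagged_reconstruct(leak, k = config$k_bags, mode = "tn",
                                n = config$tn_steps, params = config$params,
                                rng_seed = s2),
      rn_k = bagged_reconstruct(leak, k = config$k_bags, mode = "rn",
                                schedule = config$rn_schedule,
                                params = config$params, rng_seed = s2),
      stop("unknown attack ", attack, call. = FALSE))
  })
}

imr_table <- function(scores, thresholds) {
  cells <- unique(scores[c("scheme", "attack", "size", "metric")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- scores$scheme == cells$scheme[i] &
      scores$attack == cells$attack[i] &
      scores$size == cells$size[i] & scores$metric == cells$metric[i]
    sc <- scores$score[sel]
    sc <- sc[!is.na(sc)]
    data.frame(cells[i, , drop = FALSE],
               threshold = thresholds,
               imr = if (length(sc)) imr(sc, thresholds) else NA_real_,
               n_comparisons = length(sc), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
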