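#' Rotation grid of integer column shifts
#'
#' Rotation between captures is modeled as circular column shifts of the
#' row-circular lattice.  The grid holds the shifts tried during
#' matching, by default -delta..+delta columns.
#'
#' @param delta maximum absolute shift (default 8 columns).
#' @param shifts alternatively, an explicit integer vector of shifts.
#' @return An integer vector of class `rotation_grid`.
#' @export
rotation_grid <- function(delta = 8L, shifts = NULL) {
  if (is.null(shifts)) {
    delta <- as.integer(delta)
    stopifnot(delta >= 0L)
    shifts <- seq.int(-delta, delta)
  }
  shifts <- unique(as.integer(shifts))
  structure(shifts, class = "rotation_grid")
}

# circular column shift of a template: entry (r, c) of the result is the
# probe's entry at column (c + shift) mod q2 -- i.e. the alignment used
# when comparing the probe against a reference at this shift.
shift_columns <- function(t, shift) {
  q2 <- ncol(t$phase)
  src <- ((seq_len(q2) - 1L + shift) %% q2) + 1L
  iris_template(t$phase[, src, drop = FALSE], t$mask[, src, drop = FALSE])
}

#' Build the padded partial probe for one silo
#'
#' A silo holding a partial reference needs, for every allowed shift,
#' the probe bits at the column-shifted images of its reference
#' positions.  The padded partial template collects exactly those probe
#' bits (phase and mask), wrapping column arithmetic around the
#' row-circular lattice.
#'
#' @param probe an [iris_template].
#' @param reference_positions n x 2 matrix of 0-based (row, col)
#'   positions held by the silo.
#' @param grid a [rotation_grid].
#' @return A [partial_template] over the union of shifted positions.
#' @export
build_padded_probe <- function(probe, reference_positions, grid) {
  stopifnot(inherits(probe, "iris_template"))
  reference_positions <- matrix(as.integer(reference_positions), ncol = 2L)
  if (nrow(reference_positions) == 0L) {
    stop("empty reference position set", call. = FALSE)
  }
  q1 <- nrow(probe$phase); q2 <- ncol(probe$phase)
  if (any(abs(as.integer(grid)) >= q2)) {
    stop("shift magnitude must be smaller than the column count", call. = FALSE)
  }
  rows <- rep(reference_positions[, 1L], length(grid))
  cols <- (rep(reference_positions[, 2L], length(grid)) +
             rep(as.integer(grid), each = nrow(reference_positions))) %% q2
  keys <- unique(rows + cols * q1 + 1L)
  keys <- sort(keys)
  partial_from_indices(probe, keys)
}

#' Compare a padded partial probe with a partial reference at one shift
#'
#' The silo-local step: for each reference position (r, c) the probe bit
#' at (r, (c + shift) mod q2) is compared, masked on both sides.
#' Returns exact integer counts; the fractional score is their ratio.
#'
#' @param padded_probe the silo's [partial_template] of probe bits (from
#'   [build_padded_probe()]).
#' @param reference_partial the silo's stored [partial_template].
#' @param shift integer column shift.
#' @return A `partial_score`: list with `d` (fraction, `NA` when no bit
#'   is jointly valid), `mismatches`, and `a` (jointly valid count).
#' @export
partial_compare <- function(padded_probe, reference_partial, shift) {
  stopifnot(inherits(padded_probe, "partial_template"),
            inherits(reference_partial, "partial_template"))
  shape <- reference_partial$origin_shape
  if (!identical(padded_probe$origin_shape, shape)) {
    stop("probe and reference partials disagree on origin shape", call. = FALSE)
  }
  q1 <- shape[1L]; q2 <- shape[2L]
  want_rows <- reference_partial$positions[, 1L]
  want_cols <- (reference_partial$positions[, 2L] + as.integer(shift)) %% q2
  want_keys <- want_rows + want_cols * q1 + 1L
  have_keys <- pos_key(padded_probe$positions, q1)
  at <- match(want_keys, have_keys)
  if (anyNA(at)) {
    stop("padded probe does not cover all reference positions at this shift",
         call. = FALSE)
  }
  valid <- padded_probe$mask_values[at] == 1L & reference_partial$mask_values == 1L
  a <- sum(valid)
  mism <- sum(padded_probe$values[at][valid] != reference_partial$values[valid])
  structure(list(d = if (a > 0L) mism / a else NA_real_,
                 mismatches = mism, a = a),
            class = "partial_score")
}

#' Aggregate per-silo partial scores for one angle
#'
#' The central server's per-angle score is the a_ij-weighted mean of the
#' silo scores d_ij:
#' \deqn{d_{\theta_j} = \sum_i a_{ij} d_{ij} / \sum_i a_{ij}}
#' computed here from the integer counts (sum of mismatches over sum of
#' a_ij), so it equals the whole-template masked distance exactly.  The
#' function consumes only `(mismatches, a)` count pairs -- no phase bits
#' cross the silo boundary.
#'
#' @param scores list of `partial_score` objects (one per silo).
#' @return List with `value` (`NA` when every a_ij is 0), `mismatches`
#'   and `a` (the totals).
#' @export
aggregate_angle <- function(scores) {
  stopifnot(length(scores) >= 1L)
  a <- sum(vapply(scores, function(s) s$a, numeric(1L)))
  mism <- sum(vapply(scores, function(s) s$mismatches, numeric(1L)))
  list(value = if (a > 0) mism / a else NA_real_, mismatches = mism, a = a)
}

#' Distributed template matching across silos
#'
#' The full protocol: each silo receives a padded partial probe, runs
#' partial comparisons at every shift in the grid, and emits only
#' (d_ij, a_ij).  The central server aggregates per angle and takes the
#' minimum over angles.  For `metric = "mhd"` each aggregated plain
#' score is converted through [modified_from_plain()] with
#' l = sum(a_ij), so the server still needs nothing but counts.
#' Angle ties are broken toward the smallest absolute shift, then toward
#' the negative shift.
#'
#' @param probe an [iris_template].
#' @param reference_partials list of [partial_template]s partitioning
#'   the lattice.
#' @param grid a [rotation_grid].
#' @param metric `"hd"` or `"mhd"`.
#' @return List with `score`, `shift` (the minimising shift),
#'   `metric`, and `table`: a data frame of (shift, silo, d, a).
#' @export
distributed_match <- function(probe, reference_partials,
                              grid = rotation_grid(),
                              metric = c("hd", "mhd")) {
  metric <- match.arg(metric)
  stopifnot(inherits(probe, "iris_template"), length(reference_partials) >= 1L)
  N <- prod(reference_partials[[1L]]$origin_shape)
  padded <- lapply(reference_partials, function(ref) {
    build_padded_probe(probe, ref$positions, grid)
  })
  shifts <- as.integer(grid)
  order_pref <- order(abs(shifts), shifts)  # tie-break: |shift|, then negative
  rows <- list(); best <- NULL
  for (j in order_pref) {
    sh <- shifts[j]
    silo_scores <- lapply(seq_along(reference_partials), function(i) {
      partial_compare(padded[[i]], reference_partials[[i]], sh)
    })
    agg <- aggregate_angle(silo_scores)
    rows[[length(rows) + 1L]] <- data.frame(
      shift = sh, silo = seq_along(silo_scores),
      d = vapply(silo_scores, function(s) s$d, numeric(1L)),
      a = vapply(silo_scores, function(s) s$a, numeric(1L)))
    angle_score <- if (metric == "mhd") {
      modified_from_plain(if (agg$a > 0) agg$value else 0.5, agg$a, N)
    } else {
      if (agg$a == 0) next  # undefined angle under hd: skip
      agg$value
    }
    if (is.null(best) || angle_score < best$score) {
      best <- list(score = angle_score, shift = sh)
    }
  }
  if (is.null(best)) {
    stop("match rejected: no angle had any jointly valid bit", call. = FALSE)
  }
  list(score = best$score, shift = best$shift, metric = metric,
       table = do.call(rbind, rows))
}
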