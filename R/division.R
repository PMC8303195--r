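#' Divide a template into rectangular blocks
#'
#' Block-form division: the lattice is tiled by a `grid` = (rows, cols)
#' arrangement of equal rectangular blocks, giving m = rows * cols
#' partial templates.  The occlusion mask is divided identically.  The
#' default grids used elsewhere in the package are column bands
#' ((1, m)), which respect the row-circular topology used by rotation.
#'
#' @param t an [iris_template].
#' @param grid integer (rows, cols); must divide the template shape
#'   evenly.
#' @return A list of m [partial_template]s whose positions partition the
#'   lattice.
#' @examples
#' t <- iris_template(matrix(rbinom(1024, 1, 0.5), 8, 128))
#' parts <- divide_block(t, c(1, 16))   # 16 blocks of 8 x 8
#' length(parts)
#' @export
divide_block <- function(t, grid) {
  stopifnot(inherits(t, "iris_template"))
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  q1 <- nrow(t$phase); q2 <- ncol(t$phase)
  if (q1 %% grid[1L] != 0L || q2 %% grid[2L] != 0L) {
    stop(sprintf("grid (%d, %d) does not divide the %d x %d template evenly",
                 grid[1L], grid[2L], q1, q2), call. = FALSE)
  }
  br <- q1 %/% grid[1L]; bc <- q2 %/% grid[2L]
  out <- vector("list", prod(grid))
  n <- 0L
  for (u in seq_len(grid[1L])) {
    for (v in seq_len(grid[2L])) {
      rows <- ((u - 1L) * br + 1L):(u * br)
      cols <- ((v - 1L) * bc + 1L):(v * bc)
      idx <- as.vector(outer(rows, (cols - 1L) * q1, `+`))
      n <- n + 1L
      out[[n]] <- partial_from_indices(t, idx)
    }
  }
  out
}

#' Divide a template by R-dispersion
#'
#' All lattice positions are randomly permuted and partitioned into m
#' equal groups regardless of their bit values, so each partial template
#' inherits the whole template's 0/1 balance in expectation.
#' Deterministic given `rng_seed`.
#'
#' @param t an [iris_template].
#' @param m number of partial templates; must divide q1 * q2.
#' @param rng_seed integer seed for the permutation.
#' @return A list of m [partial_template]s partitioning the lattice.
#' @export
divide_r_dispersion <- function(t, m, rng_seed) {
  stopifnot(inherits(t, "iris_template"))
  m <- as.integer(m)
  N <- length(t$phase)
  if (m < 1L || N %% m != 0L) {
    stop(sprintf("m = %d must divide the template size %d", m, N),
         call. = FALSE)
  }
  perm <- with_rng_seed(rng_seed, sample.int(N))
  size <- N %/% m
  lapply(seq_len(m), function(i) {
    partial_from_indices(t, perm[((i - 1L) * size + 1L):(i * size)])
  })
}

#' Divide a template by Z-dispersion
#'
#' Each partial template is value-homogeneous: it contains only
#' 0-valued or only 1-valued positions of the original template.  The
#' positions holding 0s are randomly partitioned among m/2 partials and
#' the positions holding 1s among the other m/2, with sizes as equal as
#' integer division allows (remainders spread round-robin).
#' Deterministic given `rng_seed`.
#'
#' @param t an [iris_template].
#' @param m even number of partial templates; the template must contain
#'   at least m/2 zeros and m/2 ones.
#' @param rng_seed integer seed.
#' @return A list of m [partial_template]s partitioning the lattice;
#'   partials 1..m/2 carry zeros, partials m/2+1..m carry ones.
#' @export
divide_z_dispersion <- function(t, m, rng_seed) {
  stopifnot(inherits(t, "iris_template"))
  m <- as.integer(m)
  if (m < 2L || m %% 2L != 0L) {
    stop("Z-dispersion needs an even m >= 2", call. = FALSE)
  }
  zeros <- which(t$phase == 0L)
  ones <- which(t$phase == 1L)
  half <- m %/% 2L
  if (length(zeros) < half || length(ones) < half) {
    stop(sprintf(paste0("template has %d zeros and %d ones; Z-dispersion ",
                        "into %d partials needs at least %d of each"),
                 length(zeros), length(ones), m, half), call. = FALSE)
  }
  groups <- with_rng_seed(rng_seed, {
    c(split_round_robin(sample(zeros), half),
      split_round_robin(sample(ones), half))
  })
  lapply(groups, function(idx) partial_from_indices(t, idx))
}

# Split `x` into `g` groups whose sizes differ by at most one
# (remainder assigned to the leading groups).
split_round_robin <- function(x, g) {
  n <- length(x)
  base <- n %/% g
  extra <- n %% g
  sizes <- rep(base, g) + c(rep(1L, extra), rep(0L, g - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(g), function(i) x[starts[i]:ends[i]])
}

#' Reassemble partial templates into the original template
#'
#' The inverse of every division scheme: requires the partials'
#' positions to partition the lattice exactly (no overlap, no gap) and
#' rebuilds phase and mask.
#'
#' @param partials a list of [partial_template]s with a common origin
#'   shape.
#' @return An [iris_template].
#' @export
reassemble <- function(partials) {
  stopifnot(is.list(partials), length(partials) >= 1L)
  shape <- partials[[1L]]$origin_shape
  for (p in partials) {
    stopifnot(inherits(p, "partial_template"))
    if (!identical(p$origin_shape, shape)) {
      stop("partial templates disagree on origin shape", call. = FALSE)
    }
  }
  q1 <- shape[1L]
  keys <- unlist(lapply(partials, function(p) pos_key(p$positions, q1)))
  if (anyDuplicated(keys)) {
    stop("overlapping positions across partial templates", call. = FALSE)
  }
  if (length(keys) != prod(shape)) {
    stop(sprintf("positions do not cover the lattice: %d of %d present",
                 length(keys), prod(shape)), call. = FALSE)
  }
  phase <- matrix(NA_integer_, shape[1L], shape[2L])
  mask <- matrix(NA_integer_, shape[1L], shape[2L])
  for (p in partials) {
    rc1 <- p$positions + 1L
    phase[rc1] <- p$values
    mask[rc1] <- p$mask_values
  }
  iris_template(phase, mask)
}
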