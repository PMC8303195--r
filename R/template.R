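#' Binary phase-code templates
#'
#' An `iris_template` is the pair (C, M): a 2-D binary phase code `phase`
#' and a same-shape binary occlusion `mask` (1 = valid bit, 0 =
#' occluded/invalid).  The default shape is 8 rows by 128 columns, the
#' size of one channel (real or imaginary part) of a Gabor iris code.
#' The lattice is row-circular: the first and last column of each row are
#' horizontally adjacent, which is why at least 3 columns are required
#' (with 2, the wrap-around would duplicate an edge).
#'
#' @param phase integer/numeric matrix with entries in \{0, 1\}.
#' @param mask  same-shape matrix in \{0, 1\}; defaults to all-valid.
#' @return An object of class `iris_template` with integer fields
#'   `phase` and `mask`.
#' @examples
#' t <- iris_template(matrix(rbinom(24, 1, 0.5), 4, 6))
#' dim(t$phase)
#' @export
iris_template <- function(phase, mask = NULL) {
  phase <- as_bit_matrix(phase, "phase")
  if (is.null(mask)) {
    mask <- matrix(1L, nrow(phase), ncol(phase))
  } else {
    mask <- as_bit_matrix(mask, "mask")
  }
  if (!identical(dim(phase), dim(mask))) {
    stop("phase and mask must have identical shape", call. = FALSE)
  }
  if (nrow(phase) < 1L || ncol(phase) < 3L) {
    stop("template needs q1 >= 1 rows and q2 >= 3 columns ",
         "(row-circular adjacency would duplicate edges below 3)",
         call. = FALSE)
  }
  structure(list(phase = phase, mask = mask), class = "iris_template")
}

as_bit_matrix <- function(x, what) {
  if (!is.matrix(x)) stop(what, " must be a matrix", call. = FALSE)
  if (anyNA(x) || !all(x == 0L | x == 1L)) {
    stop(what, " entries must all be 0 or 1", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' @export
print.iris_template <- function(x, ...) {
  cat(sprintf("<iris_template %d x %d, %d/%d valid bits, %.1f%% ones>\n",
              nrow(x$phase), ncol(x$phase), sum(x$mask), length(x$mask),
              100 * mean(x$phase)))
  invisible(x)
}

template_shape <- function(t) dim(t$phase)

#' Bit/spin conversion
#'
#' The Ising modules use the spin convention: bit 0 maps to spin -1 and
#' bit 1 to spin +1.  `to_spin()` converts a template's phase matrix to a
#' spin matrix; `from_spin()` converts back to a template, attaching the
#' given occlusion mask (all-valid by default).  The two are exact
#' inverses.
#'
#' @param template an [iris_template].
#' @param spin a matrix over \{-1, +1\}.
#' @param mask optional binary mask for the rebuilt template.
#' @return `to_spin()`: an integer matrix over \{-1, +1\} of class
#'   `spin_view`; `from_spin()`: an [iris_template].
#' @examples
#' t <- iris_template(matrix(c(0, 1, 1, 0, 0, 1), 2, 3))
#' identical(from_spin(to_spin(t))$phase, t$phase)
#' @export
to_spin <- function(template) {
  stopifnot(inherits(template, "iris_template"))
  v <- 2L * template$phase - 1L
  class(v) <- c("spin_view", class(v))
  v
}

#' @rdname to_spin
#' @export
from_spin <- function(spin, mask = NULL) {
  spin <- as_spin_matrix(spin)
  iris_template((unclass(spin) + 1L) %/% 2L, mask)
}

as_spin_matrix <- function(x) {
  x <- unclass(x)
  if (!is.matrix(x)) stop("spin view must be a matrix", call. = FALSE)
  if (anyNA(x) || !all(x == -1L | x == 1L)) {
    stop("spin entries must all be -1 or +1", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Univariate (column-major) lattice indexing
#'
#' Positions on the q1 x q2 lattice are often written with a single
#' 1-based index k = i + (j - 1) q1 for row i and column j (both
#' 1-based).  `univariate_index()` computes k; `univariate_position()`
#' inverts it.  Internally the package stores positions 0-based as
#' (row, col) pairs; these helpers are the explicit bridge to the
#' 1-based column-major convention.
#'
#' @param i,j 1-based row and column indices (vectorised).
#' @param k 1-based univariate indices (vectorised).
#' @param q1 number of rows; @param q2 number of columns.
#' @return `univariate_index()`: integer k; `univariate_position()`: a
#'   two-column integer matrix of (i, j) pairs.
#' @examples
#' univariate_index(3, 2, q1 = 8)   # 11
#' univariate_position(11, q1 = 8, q2 = 128)
#' @export
univariate_index <- function(i, j, q1) {
  i <- as.integer(i); j <- as.integer(j); q1 <- as.integer(q1)
  if (any(i < 1L | i > q1) || any(j < 1L)) {
    stop("index out of range: need 1 <= i <= q1 and j >= 1", call. = FALSE)
  }
  i + (j - 1L) * q1
}

#' @rdname univariate_index
#' @export
univariate_position <- function(k, q1, q2) {
  k <- as.integer(k); q1 <- as.integer(q1); q2 <- as.integer(q2)
  if (any(k < 1L | k > q1 * q2)) {
    stop("index out of range: need 1 <= k <= q1*q2", call. = FALSE)
  }
  cbind(i = (k - 1L) %% q1 + 1L, j = (k - 1L) %/% q1 + 1L)
}

#' Partial templates
#'
#' A partial template records the three ingredients a silo stores: the
#' bit values of a subset of lattice positions, the occlusion-mask bits
#' at those positions, and the positions themselves on the original
#' lattice.  Positions are stored 0-based as (row, col) pairs.
#'
#' @param origin_shape integer vector (q1, q2) of the original lattice.
#' @param positions n x 2 integer matrix of 0-based (row, col) pairs;
#'   rows must be distinct and inside `origin_shape`.
#' @param values bit values (0/1) at the positions.
#' @param mask_values mask bits (0/1) at the positions.
#' @return An object of class `partial_template`.
#' @export
partial_template <- function(origin_shape, positions, values, mask_values) {
  origin_shape <- as.integer(origin_shape)
  stopifnot(length(origin_shape) == 2L)
  positions <- matrix(as.integer(positions), ncol = 2L)
  n <- nrow(positions)
  if (n == 0L) stop("partial template needs at least one position", call. = FALSE)
  if (any(positions[, 1L] < 0L) || any(positions[, 1L] >= origin_shape[1L]) ||
      any(positions[, 2L] < 0L) || any(positions[, 2L] >= origin_shape[2L])) {
    stop("positions outside origin shape", call. = FALSE)
  }
  key <- positions[, 1L] + positions[, 2L] * origin_shape[1L]
  if (anyDuplicated(key)) stop("duplicate positions in partial template", call. = FALSE)
  values <- as.integer(values); mask_values <- as.integer(mask_values)
  if (length(values) != n || length(mask_values) != n) {
    stop("positions, values and mask_values must have equal length", call. = FALSE)
  }
  if (!all(values %in% c(0L, 1L)) || !all(mask_values %in% c(0L, 1L))) {
    stop("values and mask_values must be 0/1", call. = FALSE)
  }
  structure(list(origin_shape = origin_shape, positions = positions,
                 values = values, mask_values = mask_values),
            class = "partial_template")
}

#' @export
print.partial_template <- function(x, ...) {
  cat(sprintf("<partial_template: %d of %d positions on a %d x %d lattice>\n",
              nrow(x$positions), prod(x$origin_shape),
              x$origin_shape[1L], x$origin_shape[2L]))
  invisible(x)
}

# Extract a partial template from `t` at 1-based column-major linear
# indices `idx`.
partial_from_indices <- function(t, idx) {
  q1 <- nrow(t$phase)
  idx <- as.integer(idx)
  rc1 <- univariate_position(idx, q1, ncol(t$phase))  # 1-based (i, j)
  partial_template(template_shape(t), rc1 - 1L,
                   t$phase[rc1], t$mask[rc1])
}

# 0-based (row, col) -> 1-based column-major linear key (for set algebra)
pos_key <- function(positions, q1) {
  positions[, 1L] + positions[, 2L] * q1 + 1L
}

#' Read and write templates as plain text
#'
#' Format: line 1 holds "q1 q2"; then q1 lines of q2 characters from
#' \{0,1\} (the phase); one blank line; then q1 lines of q2 characters
#' (the mask).  UTF-8 with LF newlines.  `read_template()` names the
#' offending line in its error message for malformed files.
#'
#' @param path file path.
#' @param template an [iris_template].
#' @return `read_template()` returns an [iris_template];
#'   `write_template()` returns `path` invisibly.
#' @export
read_template <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("line 1: empty template file", call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("line 1: expected header 'q1 q2'", call. = FALSE)
  }
  q1 <- hdr[1L]; q2 <- hdr[2L]
  if (length(lines) < 1L + q1 + 1L + q1) {
    stop(sprintf("line %d: truncated file, expected %d lines",
                 length(lines) + 1L, 2L * q1 + 2L), call. = FALSE)
  }
  parse_block <- function(offset, what) {
    out <- matrix(0L, q1, q2)
    for (r in seq_len(q1)) {
      ln <- offset + r
      chars <- strsplit(lines[ln], "")[[1L]]
      if (length(chars) != q2) {
        stop(sprintf("line %d: %s row has %d characters, expected %d",
                     ln, what, length(chars), q2), call. = FALSE)
      }
      if (!all(chars %in% c("0", "1"))) {
        stop(sprintf("line %d: non-binary character in %s", ln, what),
             call. = FALSE)
      }
      out[r, ] <- as.integer(chars)
    }
    out
  }
  phase <- parse_block(1L, "phase")
  if (nzchar(trimws(lines[q1 + 2L]))) {
    stop(sprintf("line %d: expected blank separator line", q1 + 2L),
         call. = FALSE)
  }
  mask <- parse_block(q1 + 2L, "mask")
  iris_template(phase, mask)
}

#' @rdname read_template
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "iris_template"))
  q1 <- nrow(template$phase)
  row_strings <- function(m) {
    vapply(seq_len(q1), function(r) paste0(m[r, ], collapse = ""), character(1L))
  }
  writeLines(c(paste(dim(template$phase), collapse = " "),
               row_strings(template$phase), "", row_strings(template$mask)),
             path)
  invisible(path)
}

#' Read and write partial templates as JSON
#'
#' Keys: `origin_shape` (\[q1, q2\]), `positions` (list of 0-based
#' \[row, col\] pairs), `values` and `mask` (lists of 0/1).
#'
#' @param path file path.
#' @param partial a [partial_template].
#' @return `read_partial()` returns a [partial_template];
#'   `write_partial()` returns `path` invisibly.
#' @export
read_partial <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  partial_template(obj$origin_shape, matrix(obj$positions, ncol = 2L),
                   obj$values, obj$mask)
}

#' @rdname read_partial
#' @export
write_partial <- function(partial, path) {
  stopifnot(inherits(partial, "partial_template"))
  obj <- list(origin_shape = partial$origin_shape,
              positions = unname(partial$positions),
              values = partial$values,
              mask = partial$mask_values)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}
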