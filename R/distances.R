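#' Masked fractional Hamming distance
#'
#' The dissimilarity score between templates A = (C_A, M_A) and
#' B = (C_B, M_B):
#' \deqn{d_H(A,B) = \frac{\|(C_A \otimes C_B) \cap M_A \cap M_B\|}
#'                       {\|M_A \cap M_B\|}}
#' i.e. the fraction of disagreeing phase bits among the l positions
#' where both masks are valid.  Counts are kept as exact integers and
#' divided once, so equal inputs give bit-identical scores.
#'
#' @param a,b same-shape [iris_template]s.
#' @return A `dissimilarity_score`: list with `value`, `mismatches`
#'   (the XOR count), `l` (compared bits), `N` (total bits) and
#'   `metric`.
#' @seealso [modified_hamming_distance()] for the occlusion-penalising
#'   variant, which is defined even when no bits are jointly valid.
#' @examples
#' a <- iris_template(matrix(c(0,1,0,1,0,0,1,1), 2, 4, byrow = TRUE))
#' b <- iris_template(matrix(c(0,1,0,0,1,0,1,1), 2, 4, byrow = TRUE))
#' hamming_distance(a, b)$value  # 2/8
#' @export
hamming_distance <- function(a, b) {
  counts <- mismatch_counts(a, b)
  if (counts$l == 0L) {
    stop("Hamming distance undefined: no jointly valid bits (l = 0); ",
         "use modified_hamming_distance()", call. = FALSE)
  }
  dissimilarity_score(counts$mismatches / counts$l, counts, "hd")
}

#' Modified (occlusion-penalising) Hamming distance
#'
#' Assigns a score of 0.5 to every jointly invalid bit:
#' \deqn{d_H'(A,B) = \frac{\|(C_A \otimes C_B) \cap M_A \cap M_B\|}{N}
#'                 + 0.5\,\frac{\|\sim(M_A \cap M_B)\|}{N}}
#' This penalises probes that blank out most of their mask (the
#' "occlusion attack"): a fully occluded comparison scores 0.5 rather
#' than being undefined.
#'
#' @inheritParams hamming_distance
#' @return A `dissimilarity_score` (see [hamming_distance()]).
#' @export
modified_hamming_distance <- function(a, b) {
  counts <- mismatch_counts(a, b)
  value <- counts$mismatches / counts$N + 0.5 * (counts$N - counts$l) / counts$N
  dissimilarity_score(value, counts, "mhd")
}

mismatch_counts <- function(a, b) {
  stopifnot(inherits(a, "iris_template"), inherits(b, "iris_template"))
  if (!identical(dim(a$phase), dim(b$phase))) {
    stop("templates must have the same shape", call. = FALSE)
  }
  valid <- a$mask == 1L & b$mask == 1L
  list(mismatches = sum(a$phase[valid] != b$phase[valid]),
       l = sum(valid), N = length(a$phase))
}

dissimilarity_score <- function(value, counts, metric) {
  structure(list(value = value, mismatches = counts$mismatches,
                 l = counts$l, N = counts$N, metric = metric),
            class = "dissimilarity_score")
}

#' @export
print.dissimilarity_score <- function(x, ...) {
  cat(sprintf("<%s = %.6f (mismatches %d, l = %d, N = %d)>\n",
              x$metric, x$value, x$mismatches, x$l, x$N))
  invisible(x)
}

#' Bridge between plain and modified Hamming distance
#'
#' The two metrics are linked by
#' \deqn{d_H' = 0.5 - (0.5 - d_H)\,l/N}
#' where l is the number of bits actually compared and N the template
#' size.  With full overlap (l = N) this collapses to d_H; with no
#' overlap (l = 0) it is 0.5 regardless of d_H.
#'
#' @param dh plain fractional Hamming distance in \[0, 1\].
#' @param l number of jointly valid bits, 0 <= l <= n.
#' @param n total number of bits, n > 0.
#' @return The modified Hamming distance.
#' @examples
#' modified_from_plain(0.2, 256, 1024)  # 0.425
#' @export
modified_from_plain <- function(dh, l, n) {
  if (any(dh < 0) || any(dh > 1)) stop("dh must lie in [0, 1]", call. = FALSE)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(l < 0) || any(l > n)) stop("need 0 <= l <= n", call. = FALSE)
  0.5 - (0.5 - dh) * l / n
}
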