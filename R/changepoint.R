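#' Largest-magnitude single change point by residual-sum-of-squares
#'
#' Fits a two-segment piecewise-constant mean model at every admissible split
#' of a numeric sequence and returns the split minimizing the total residual
#' sum of squares. The returned index is the first element of the post-change
#' segment. Ties are broken toward the earliest index. A constant sequence has
#' no change point (magnitude 0).
#'
#' This is the engine behind both the session-level seeking change point
#' (binary approach sequences across trials) and the within-trial approach
#' initiation time (real-valued approach-likelihood traces).
#'
#' @param x numeric sequence, length >= 4.
#' @param min_seg minimum segment length on either side of the split
#'   (default 2).
#' @return list with `index` (first post-change element, 1-based; `NA` if no
#'   change point), `magnitude` (absolute difference of segment means),
#'   `rss_drop` (residual-error reduction relative to the single-mean fit).
#' @export
#' @examples
#' change_point_rss(c(1, 1, 1, 1, 0, 0, 0, 0)) # index 5, magnitude 1
change_point_rss <- function(x, min_seg = 2L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("change_point_rss: sequence must have length >= 4, got ", n)
  if (anyNA(x)) stop("change_point_rss: sequence contains missing values")
  if (max(x) == min(x)) {
    return(list(index = NA_integer_, magnitude = 0, rss_drop = 0))
  }
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # candidate first-post indices k: pre = 1..k-1, post = k..n
  ks <- seq.int(min_seg + 1L, n - min_seg + 1L)
  n1 <- ks - 1
  n2 <- n - n1
  s1 <- cs[ks - 1L]
  s2 <- cs[n] - s1
  q1 <- cs2[ks - 1L]
  q2 <- cs2[n] - q1
  rss <- (q1 - s1^2 / n1) + (q2 - s2^2 / n2)
  rss0 <- cs2[n] - cs[n]^2 / n
  # exact ties (frequent for binary sequences) break toward the earliest
  # index; the tolerance absorbs floating-point noise in the cumsum formula
  tol <- 1e-9 * (1 + abs(rss0))
  best <- which(rss - min(rss) <= tol)[1]
  k <- ks[best]
  m1 <- s1[best] / n1[best]
  m2 <- s2[best] / n2[best]
  list(index = as.integer(k),
       magnitude = abs(m2 - m1),
       rss_drop = rss0 - rss[best])
}

#' Session seeking-state change point
#'
#' Finds the trial at which the animal's approach behavior switches from the
#' high-approach (seeking) to the low-approach (not-seeking) state, as the
#' largest-magnitude change point of the binary approach sequence in CS+
#' trial order.
#'
#' @param approach_sequence binary (0/1 or logical) vector, one element per
#'   CS+ trial in time order.
#' @param min_seg minimum trials per segment (default 2).
#' @return list with `j_scp` (first trial of the post-change, low-seeking
#'   segment; `NA` when the sequence is constant), `magnitude` and
#'   `rss_drop` as in [change_point_rss()].
#' @export
session_change_point <- function(approach_sequence, min_seg = 2L) {
  cp <- change_point_rss(as.numeric(approach_sequence), min_seg = min_seg)
  list(j_scp = cp$index, magnitude = cp$magnitude, rss_drop = cp$rss_drop)
}
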