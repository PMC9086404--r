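#' Discretize a numeric series into trend symbols
#'
#' Converts a series \eqn{X_1, \dots, X_n} into the trend sequence
#' \eqn{d_1, \dots, d_{n-1}} over \{-1, 0, +1\}: for \eqn{X_i \neq 0} the
#' relative change \eqn{(X_{i+1} - X_i)/|X_i|} is compared against the
#' threshold \eqn{t} (symbol +1 when \eqn{\ge t}, -1 when \eqn{\le -t}, 0
#' strictly in between); for \eqn{X_i = 0} the symbol is the sign of
#' \eqn{X_{i+1}}. With `t = 0` a series without exact zeros yields a
#' two-state sequence over \{-1, +1\}; note that consecutive *equal* values
#' then give a relative change of 0, which satisfies the inclusive
#' \eqn{\ge t} rule and is coded +1 (set `strict = TRUE` for strict
#' inequalities, under which ties at the threshold become 0). Zero-heavy
#' abundance tables should be aware of this convention.
#'
#' @param x numeric vector, length at least 2, no missing values (see
#'   [interpolate_missing()] for tables with gaps).
#' @param t non-negative trend threshold; `t = 0` gives the two-state coding.
#' @param strict logical; use strict inequalities at the threshold.
#' @return An integer vector of class `"trend_series"`, length
#'   `length(x) - 1`, with attributes `threshold` and `strict`.
#' @examples
#' trend_discretize(c(1, 2, 3, 4), t = 0)
#' trend_discretize(c(1, 1.4, 0.6, 0.6), t = 0.5)
#' @export
trend_discretize <- function(x, t = 0, strict = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("need at least 2 observations to form a trend series")
  if (anyNA(x) || any(!is.finite(x)))
    stop("series contains missing or non-finite values")
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("'t' must be a single non-negative number")
  d <- discretize_cpp(x, t, isTRUE(strict))
  structure(d, threshold = t, strict = isTRUE(strict),
            class = "trend_series")
}

#' @export
print.trend_series <- function(x, ...) {
  cat("Trend series (m = ", length(x), ", t = ", attr(x, "threshold"),
      ")\n", sep = "")
  print(as.integer(x))
  invisible(x)
}

#' Observed trend states
#'
#' The set of distinct symbols actually present in a trend sequence; used to
#' decide between the two-state, three-state and mixed Markov variance
#' models.
#'
#' @param d trend symbol vector (from [trend_discretize()] or raw integers
#'   in \{-1, 0, 1\}).
#' @return Sorted integer vector of distinct symbols.
#' @export
trend_states <- function(d) sort(unique(as.integer(d)))

as_trend_symbols <- function(d, arg = "d") {
  d <- as.integer(d)
  if (length(d) < 1L) stop("'", arg, "' must have length at least 1")
  if (anyNA(d) || !all(d %in% c(-1L, 0L, 1L)))
    stop("'", arg, "' must contain only symbols -1, 0, 1")
  d
}

#' Local trend score by dynamic programming
#'
#' The local trend score with maximum delay `D` is the maximum, over all
#' aligned windows whose start offset differs by at most `D`, of the summed
#' products of the two trend sequences:
#' \deqn{LT(D) = \max_{|i-j| \le D,\, k \ge 0} \sum_{l=0}^{k-1}
#'   d^X_{i+l} d^Y_{j+l}.}
#' The empty window (`k = 0`) is admissible, so the score is never negative.
#' Runs in O(m (2D+1)) time. Among score ties the reported alignment has the
#' smallest `start_x`, then `start_y`, then `length`.
#'
#' @param dx,dy trend symbol vectors of equal length (integer -1/0/1 or
#'   [trend_discretize()] output).
#' @param D non-negative integer maximum start delay.
#' @return A list of class `"lt_result"` with elements `score`, `start_x`,
#'   `start_y` (1-based starts, `NA` for the empty alignment), `length`,
#'   `delay` and `m`.
#' @examples
#' lt_score(c(1, 1, -1), c(1, -1, -1), D = 0)
#' lt_score(c(1, -1), c(-1, 1), D = 1)
#' @export
lt_score <- function(dx, dy, D = 0) {
  dx <- as_trend_symbols(dx, "dx")
  dy <- as_trend_symbols(dy, "dy")
  if (length(dx) != length(dy))
    stop("'dx' and 'dy' must have equal length")
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 0L)
    stop("'D' must be a single non-negative integer")
  res <- lt_score_cpp(dx, dy, D)
  new_lt_result(res, D, length(dx))
}

new_lt_result <- function(res, D, m) {
  empty <- res$length == 0L
  structure(
    list(score = as.integer(res$score),
         start_x = if (empty) NA_integer_ else res$start_x,
         start_y = if (empty) NA_integer_ else res$start_y,
         length = as.integer(res$length),
         delay = as.integer(D), m = as.integer(m)),
    class = "lt_result")
}

#' @export
print.lt_result <- function(x, ...) {
  cat("Local trend score LT(", x$delay, ") = ", x$score, sep = "")
  if (x$length > 0L)
    cat("  [x ", x$start_x, "..", x$start_x + x$length - 1L,
        " vs y ", x$start_y, "..", x$start_y + x$length - 1L, "]",
        sep = "")
  else cat("  [empty alignment]")
  cat("\n")
  invisible(x)
}

#' Exhaustive local trend score (test oracle)
#'
#' Computes the same quantity as [lt_score()] by enumerating every start
#' pair and window length, with the same tie-breaking. Cubic in the sequence
#' length; intended for verification on short sequences.
#'
#' @inheritParams lt_score
#' @return As [lt_score()].
#' @export
lt_score_bruteforce <- function(dx, dy, D = 0) {
  dx <- as_trend_symbols(dx, "dx")
  dy <- as_trend_symbols(dy, "dy")
  if (length(dx) != length(dy))
    stop("'dx' and 'dy' must have equal length")
  m <- length(dx)
  if (m > 200L) stop("brute-force oracle is limited to m <= 200")
  best <- list(score = 0L, start_x = 0L, start_y = 0L, length = 0L)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (abs(i - j) > D) next
      kmax <- min(m - i, m - j) + 1L
      s <- 0L
      for (k in seq_len(kmax)) {
        s <- s + dx[i + k - 1L] * dy[j + k - 1L]
        if (s > best$score ||
            (s == best$score && s > 0L &&
             (i < best$start_x ||
              (i == best$start_x &&
               (j < best$start_y ||
                (j == best$start_y && k < best$length)))))) {
          best <- list(score = s, start_x = i, start_y = j, length = k)
        }
      }
    }
  }
  new_lt_result(best, D, m)
}
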