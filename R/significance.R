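#' Brownian extremum tail function
#'
#' Approximate upper-tail probability of the scaled local trend score,
#' \deqn{L_D(x) = 1 - \Theta(x)^{2D+1},}
#' where \eqn{\Theta(x) = P(\max_{0 \le v \le 1} |W_v| \le x)} for a
#' standard Brownian motion \eqn{W}, evaluated by the alternating theta
#' series
#' \deqn{\Theta(x) = \frac{4}{\pi} \sum_{k \ge 0} \frac{(-1)^k}{2k+1}
#'   \exp\!\left(-\frac{(2k+1)^2 \pi^2}{8 x^2}\right).}
#' The series is truncated when a term falls below 1e-14 (at most 1000
#' terms); `x` below 1e-8 returns 1 outright, where the series converges
#' slowly but the answer is 1.
#'
#' @param x non-negative scaled statistic (vectorized).
#' @param D non-negative integer maximum delay.
#' @return Tail probabilities in `[0, 1]`, decreasing in `x` and
#'   non-decreasing in `D`.
#' @examples
#' lta_tail(2.5, D = 0)
#' @export
lta_tail <- function(x, D = 0) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 0L)
    stop("'D' must be a single non-negative integer")
  vapply(as.numeric(x), function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= 1e-8) return(1)
    if (!is.finite(xi)) return(0)
    min(1, max(0, 1 - theta_max_abs(xi)^(2 * D + 1)))
  }, numeric(1))
}

theta_max_abs <- function(x) {
  if (x > 1.5) {
    # reflection (Poisson-summed) series, rapidly convergent for large x:
    # Theta(x) = sum_k (-1)^k [Phi((2k+1)x) - Phi((2k-1)x)]
    s <- 0
    for (k in 0:999) {
      term <- stats::pnorm((2 * k + 1) * x) -
        stats::pnorm((2 * k - 1) * x)
      if (k > 0) term <- 2 * (-1)^k * term  # +/-k pairs coincide
      s <- s + term
      if (k > 0 && abs(term) < 1e-14) break
    }
    return(min(1, max(0, s)))
  }
  # theta series, rapidly convergent for small x
  s <- 0
  for (k in 0:999) {
    term <- (-1)^k / (2 * k + 1) * exp(-(2 * k + 1)^2 * pi^2 / (8 * x^2))
    s <- s + term
    if (abs(term) < 1e-14) break
  }
  min(1, max(0, 4 / pi * s))
}

#' Theoretical p-value for a local trend score
#'
#' Scales the score by \eqn{\sigma\sqrt{m}}, where `m` is the trend-sequence
#' length (one less than the original series length), and applies the
#' Brownian tail law [lta_tail()]. A score of 0 maps to p = 1.
#'
#' @param score non-negative integer local trend score.
#' @param m trend-sequence length used for scaling.
#' @param sigma long-run standard deviation of the product trend chain.
#' @param D maximum delay used when scoring.
#' @return List with `x` (the scaled statistic) and `p_value`.
#' @export
lta_pvalue <- function(score, m, sigma, D = 0) {
  if (m < 1) stop("'m' must be at least 1")
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive number")
  x <- score / (sigma * sqrt(m))
  p <- if (score <= 0) 1 else lta_tail(x, D)
  list(x = x, p_value = p)
}

# classify the pair of trend sequences and compute sigma^2 under the null
fit_state_model <- function(dx, dy) {
  fit_one <- function(d) {
    st <- trend_states(d)
    if (length(st) < 2L)
      return(list(model = "degenerate",
                  reason = "constant trend sequence"))
    counts <- pair_counts(d)
    if (!0L %in% st) {
      list(model = "two", params = estimate_two_state(counts))
    } else if (sum(counts["0", ]) == 0L) {
      # 0 occurs only as the final symbol: no observed exits from 0
      list(model = "two", params = estimate_two_state(counts))
    } else if (sum(counts["-1", ]) == 0L && sum(counts["1", ]) == 0L) {
      list(model = "degenerate",
           reason = "no transitions out of the trending states")
    } else {
      list(model = "three", params = estimate_three_state(counts))
    }
  }
  fx <- fit_one(dx)
  fy <- fit_one(dy)
  if (identical(fx$model, "degenerate") ||
      identical(fy$model, "degenerate")) {
    return(list(degenerate = TRUE, state_model = NA_character_,
                reason = c(fx$reason, fy$reason)[1]))
  }
  model <- if (fx$model == "two" && fy$model == "two") "two"
           else if (fx$model == "three" && fy$model == "three") "three"
           else "mixed"
  sigma2 <- tryCatch(
    switch(model,
           two = sigma2_two(fx$params, fy$params),
           three = sigma2_three(fx$params, fy$params),
           mixed = sigma2_mixed(fx$params, fy$params)),
    error = function(e) NULL)
  if (is.null(sigma2) || !is.finite(sigma2) || sigma2 <= 0) {
    return(list(degenerate = TRUE, state_model = model,
                reason = "non-ergodic estimated chain"))
  }
  list(degenerate = FALSE, state_model = model, sigma2 = sigma2,
       params_x = fx$params, params_y = fy$params)
}

# sigma^2 implied by an i.i.d. original series, per the chain types present
tlta_sigma2 <- function(dx, dy, t) {
  if (t == 0) {
    p <- iid_params(0)
    list(state_model = "two", sigma2 = sigma2_two(p, p))
  } else {
    p <- iid_params(t)
    list(state_model = "three", sigma2 = sigma2_three(p, p))
  }
}

#' Local trend analysis of a pair of time series
#'
#' Discretizes both series into trend symbols at threshold `t`, computes the
#' local trend score with maximum delay `D`, and assesses significance by
#' one of three methods. `"stlta"` (the default) fits Markov transition
#' matrices to the observed trend chains, computes the long-run variance of
#' their product chain under the null of independence, and applies the
#' Brownian extremum tail law -- valid for dependent (stationary) series.
#' `"tlta"` applies the same tail law but with the variance implied by
#' i.i.d. original series. `"permutation"` re-scores `n_perm` shuffles of
#' `y` against `x`; the p-value uses the add-one rule
#' \eqn{(1 + \#\{s^* \ge s\})/(n_{perm} + 1)} and is reproducible under
#' [set.seed()]. What is shuffled is controlled by `permute`:
#' `"symbols"` (default) shuffles the trend symbols of `y`, the convention
#' under which the permutation null ignores the serial dependence that
#' discretization induces even for i.i.d. data (and the one that matches
#' the published calibration tables); `"values"` shuffles the original
#' numeric values and re-discretizes, which is an exact test when the
#' values of `y` are exchangeable.
#'
#' @param x,y equal-length numeric series (length at least 3), no missing
#'   values.
#' @param t non-negative trend threshold (`t = 0`: two-state coding).
#' @param D non-negative integer maximum start delay.
#' @param method `"stlta"`, `"tlta"` or `"permutation"`.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param permute what the permutation test shuffles: trend `"symbols"` or
#'   original `"values"`.
#' @param strict logical; strict inequalities at the discretization
#'   threshold.
#' @return An object of class `"lta"`: a list with the score and alignment,
#'   `m`, `sigma`, scaled statistic `x_stat`, `p_value`, `method`,
#'   `state_model`, `degenerate` flag and (for the permutation method)
#'   `n_perm`. Degenerate chains (e.g. a strictly monotone series, whose
#'   trend sequence is constant) carry `degenerate = TRUE` and no p-value.
#' @examples
#' set.seed(1)
#' x <- cumsum(rnorm(60))
#' y <- x + rnorm(60, sd = 0.5)
#' lta(x, y, t = 0, D = 0)
#' @export
lta <- function(x, y, t = 0, D = 0,
                method = c("stlta", "tlta", "permutation"),
                n_perm = 1000, permute = c("symbols", "values"),
                strict = FALSE) {
  permute <- match.arg(permute)
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 time points")
  dx <- trend_discretize(x, t, strict)
  dy <- trend_discretize(y, t, strict)
  sc <- lt_score(dx, dy, D)
  m <- length(dx)
  out <- list(score = sc$score, alignment = sc, m = m,
              t = t, D = as.integer(D), method = toupper(method),
              sigma = NA_real_, x_stat = NA_real_, p_value = NA_real_,
              state_model = NA_character_, degenerate = FALSE,
              reason = NULL, n_perm = NULL,
              series_names = c(deparse1(substitute(x)),
                               deparse1(substitute(y))))
  if (method == "permutation") {
    n_perm <- as.integer(n_perm)
    if (n_perm < 1L) stop("'n_perm' must be at least 1")
    perm <- if (permute == "symbols")
      perm_scores_sym_cpp(dx, dy, as.integer(D), n_perm)
    else perm_scores_cpp(dx, y, t, isTRUE(strict), as.integer(D), n_perm)
    out$n_perm <- n_perm
    out$p_value <- (1 + sum(perm >= sc$score)) / (n_perm + 1)
  } else {
    fit <- if (method == "stlta") fit_state_model(dx, dy)
           else c(list(degenerate = FALSE), tlta_sigma2(dx, dy, t))
    out$state_model <- fit$state_model
    if (isTRUE(fit$degenerate)) {
      out$degenerate <- TRUE
      out$reason <- fit$reason
    } else {
      out$sigma <- sqrt(fit$sigma2)
      pv <- lta_pvalue(sc$score, m, out$sigma, D)
      out$x_stat <- pv$x
      out$p_value <- pv$p_value
    }
  }
  class(out) <- "lta"
  out
}

#' @export
print.lta <- function(x, digits = 4, ...) {
  cat("Local trend analysis (", x$method, ")\n", sep = "")
  cat("  LT(", x$D, ") = ", x$score, " on m = ", x$m,
      " trend steps (t = ", x$t, ")\n", sep = "")
  if (x$alignment$length > 0L)
    cat("  alignment: x ", x$alignment$start_x, "..",
        x$alignment$start_x + x$alignment$length - 1L, " vs y ",
        x$alignment$start_y, "..",
        x$alignment$start_y + x$alignment$length - 1L, "\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate chain (", x$reason, "): no p-value\n", sep = "")
  } else if (x$method == "PERMUTATION") {
    cat("  p = ", format(x$p_value, digits = digits), " (",
        x$n_perm, " permutations)\n", sep = "")
  } else {
    cat("  state model: ", x$state_model,
        ", sigma = ", format(x$sigma, digits = digits),
        ", x = ", format(x$x_stat, digits = digits),
        ", p = ", format(x$p_value, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.lta <- function(object, ...) {
  structure(object, class = c("summary.lta", "lta"))
}

#' @export
print.summary.lta <- function(x, ...) {
  print.lta(x, ...)
  cat("  interpretation: the score is the best co-trending aligned window;",
      "\n  under the null the scaled score follows the max-|W| Brownian law.\n")
  invisible(x)
}

#' Plot the aligned trend windows of a pair
#'
#' Draws both standardized series and shades the optimal co-trending window
#' reported by the score.
#'
#' @param x an `"lta"` object.
#' @param series optional list with elements `x` and `y` holding the
#'   original numeric series (they are not stored in the result object).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.lta <- function(x, series = NULL, ...) {
  if (is.null(series))
    stop("supply 'series = list(x = ..., y = ...)' with the original data")
  sx <- scale(series$x)[, 1]
  sy <- scale(series$y)[, 1]
  graphics::matplot(cbind(sx, sy), type = "l", lty = 1,
                    col = c("#1b6ca8", "#c0392b"),
                    xlab = "time point", ylab = "standardized value", ...)
  if (x$alignment$length > 0L) {
    from <- min(x$alignment$start_x, x$alignment$start_y)
    to <- max(x$alignment$start_x, x$alignment$start_y) +
      x$alignment$length
    graphics::rect(from, graphics::par("usr")[3], to,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  graphics::legend("topleft", legend = c("x", "y"), lty = 1,
                   col = c("#1b6ca8", "#c0392b"), bty = "n")
  invisible(x)
}
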