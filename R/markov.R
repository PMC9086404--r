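#' Markov transition parameter containers
#'
#' The trend sequences form (approximately) stationary symmetric Markov
#' chains. The two-state chain on \{-1, +1\} is parameterized by the stay
#' probability `a` (`T[-1,-1] = T[1,1] = a`); its lag-k autocovariance decays
#' as `(2a - 1)^k`. The three-state chain on \{-1, 0, +1\} has stay
#' probability `b` from the trending states, flip probability `c`
#' (`T[-1,1] = T[1,-1] = c`) and exit probability `d` from 0 to each of
#' \eqn{\pm1}; its stationary law puts
#' \eqn{\varphi_1 = \varphi_{-1} = d / (1 - b - c + 2d)} on the trending
#' states and decays as \eqn{(b - c)^k}.
#'
#' @param a,b,c,d transition probabilities as described above.
#' @return An object of class `"two_state_params"` (fields `a` and the
#'   decay factor `r` = 2a - 1) or `"three_state_params"` (fields `b`,
#'   `c`, `d`, `phi1` and the decay factor `rho` = b - c).
#' @export
two_state_params <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
    stop("'a' must be a probability in [0, 1]")
  structure(list(a = a, r = 2 * a - 1), class = "two_state_params")
}

#' @rdname two_state_params
#' @export
three_state_params <- function(b, c, d) {
  for (p in list(b = b, c = c, d = d))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
      stop("'b', 'c', 'd' must be non-negative probabilities")
  if (b + c > 1 + 1e-12) stop("'b' + 'c' must not exceed 1")
  if (2 * d > 1 + 1e-12) stop("2 * 'd' must not exceed 1")
  denom <- 1 - b - c + 2 * d
  if (denom <= 0)
    stop("degenerate chain: stationary law undefined (1 - b - c + 2d <= 0)")
  structure(list(b = b, c = c, d = d, phi1 = d / denom, rho = b - c),
            class = "three_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("Two-state trend chain: a = %.4f (decay r = %.4f)\n",
              x$a, x$r))
  invisible(x)
}

#' @export
print.three_state_params <- function(x, ...) {
  cat(sprintf(
    "Three-state trend chain: b = %.4f, c = %.4f, d = %.4f (phi1 = %.4f, decay rho = %.4f)\n",
    x$b, x$c, x$d, x$phi1, x$rho))
  invisible(x)
}

#' Transition matrix of a trend chain
#'
#' States are ordered (-1, 0, +1) for the three-state model and (-1, +1) for
#' the two-state model.
#'
#' @param params a `two_state_params` or `three_state_params` object.
#' @return A stochastic matrix with dimnames giving the states.
#' @export
transition_matrix <- function(params) {
  if (inherits(params, "two_state_params")) {
    a <- params$a
    matrix(c(a, 1 - a, 1 - a, a), 2, 2, byrow = TRUE,
           dimnames = list(c("-1", "1"), c("-1", "1")))
  } else if (inherits(params, "three_state_params")) {
    b <- params$b; c <- params$c; d <- params$d
    matrix(c(b, 1 - b - c, c,
             d, 1 - 2 * d, d,
             c, 1 - b - c, b), 3, 3, byrow = TRUE,
           dimnames = list(c("-1", "0", "1"), c("-1", "0", "1")))
  } else stop("unknown parameter class")
}

#' Adjacent symbol pair counts
#'
#' Tally of consecutive symbol pairs (d_i, d_{i+1}) in a trend sequence, the
#' sufficient statistic for the transition probability estimators.
#'
#' @param d trend symbol vector of length at least 2.
#' @return A 3x3 integer matrix with dimnames `-1, 0, 1` (rows = from,
#'   columns = to); entries sum to `length(d) - 1`.
#' @examples
#' pair_counts(c(1, 1, -1, 1))
#' @export
pair_counts <- function(d) {
  d <- as_trend_symbols(d)
  if (length(d) < 2L) stop("need at least 2 symbols to count pairs")
  u <- d[-length(d)]
  v <- d[-1L]
  idx <- (u + 1L) * 3L + (v + 2L)  # 1..9 over (from, to)
  counts <- tabulate(idx, nbins = 9L)
  matrix(counts, 3L, 3L, byrow = TRUE,
         dimnames = list(c("-1", "0", "1"), c("-1", "0", "1")))
}

row_ratio <- function(counts, num_m1, num_p1) {
  n_m1 <- sum(counts["-1", ])
  n_p1 <- sum(counts["1", ])
  if (n_m1 > 0L && n_p1 > 0L) 0.5 * (num_m1 / n_m1 + num_p1 / n_p1)
  else if (n_m1 > 0L) num_m1 / n_m1
  else if (n_p1 > 0L) num_p1 / n_p1
  else stop("degenerate trend sequence: no transitions out of -1 or +1")
}

#' Estimate two-state transition parameters
#'
#' The stay probability is estimated as the mean of the two observed row
#' ratios, \eqn{\hat a = (n_{-1,-1}/n_{-1,\cdot} + n_{1,1}/n_{1,\cdot})/2}.
#' If exactly one of the rows is unobserved the single observed ratio is
#' used; if neither row is observed the input is degenerate.
#'
#' @param counts pair-count matrix from [pair_counts()].
#' @return A `two_state_params` object.
#' @examples
#' estimate_two_state(pair_counts(c(1, 1, -1, 1)))
#' @export
estimate_two_state <- function(counts) {
  two_state_params(row_ratio(counts, counts["-1", "-1"], counts["1", "1"]))
}

#' Estimate three-state transition parameters
#'
#' \eqn{\hat b} and \eqn{\hat c} average the stay and flip ratios of the two
#' trending rows as in [estimate_two_state()];
#' \eqn{\hat d = (n_{0,-1} + n_{0,1}) / (2 n_{0,\cdot})}.
#'
#' @param counts pair-count matrix from [pair_counts()].
#' @return A `three_state_params` object.
#' @export
estimate_three_state <- function(counts) {
  n0 <- sum(counts["0", ])
  if (n0 == 0L)
    stop("no transitions out of state 0; use the two-state model")
  b <- row_ratio(counts, counts["-1", "-1"], counts["1", "1"])
  c <- row_ratio(counts, counts["-1", "1"], counts["1", "-1"])
  d <- 0.5 * (counts["0", "-1"] + counts["0", "1"]) / n0
  three_state_params(b, c, d)
}

decay_factor <- function(params) {
  if (inherits(params, "two_state_params")) params$r else params$rho
}

second_moment <- function(params) {
  # E(d_1^2): 1 for the two-state chain, 2*phi1 for the three-state chain
  if (inherits(params, "two_state_params")) 1 else 2 * params$phi1
}

check_ergodic <- function(g, tol = 1e-9) {
  if (abs(g) >= 1 - tol)
    stop("degenerate chain: |decay product| too close to 1")
}

#' Long-run variance of the product trend chain
#'
#' Under the null of independence the product chain \eqn{Z_i = d^X_i d^Y_i}
#' has long-run variance
#' \eqn{\sigma^2 = E(Z_1^2) + 2\sum_{k\ge1} E(d^X_1 d^X_{k+1})
#' E(d^Y_1 d^Y_{k+1})}, which sums in closed geometric form. For two
#' two-state chains \eqn{\sigma^2 = (1 + r_X r_Y)/(1 - r_X r_Y)} with
#' \eqn{r = 2a - 1}; for two three-state chains
#' \eqn{\sigma^2 = 4\varphi_1^X \varphi_1^Y (1 + \rho_X \rho_Y) /
#' (1 - \rho_X \rho_Y)} with \eqn{\rho = b - c}; the mixed case combines one
#' factor of each kind. `sigma2_mixed()` accepts its arguments in either
#' order.
#'
#' @param px,py parameter objects for the two chains.
#' @param p2 a `two_state_params` object.
#' @param p3 a `three_state_params` object.
#' @return The variance \eqn{\sigma^2} (positive scalar).
#' @examples
#' sigma2_two(two_state_params(0.75), two_state_params(0.75))
#' @export
sigma2_two <- function(px, py) {
  stopifnot(inherits(px, "two_state_params"),
            inherits(py, "two_state_params"))
  g <- px$r * py$r
  check_ergodic(g)
  (1 + g) / (1 - g)
}

#' @rdname sigma2_two
#' @export
sigma2_three <- function(px, py) {
  stopifnot(inherits(px, "three_state_params"),
            inherits(py, "three_state_params"))
  g <- px$rho * py$rho
  check_ergodic(g)
  4 * px$phi1 * py$phi1 * (1 + g) / (1 - g)
}

#' @rdname sigma2_two
#' @export
sigma2_mixed <- function(p2, p3) {
  if (inherits(p2, "three_state_params") &&
      inherits(p3, "two_state_params")) {
    tmp <- p2; p2 <- p3; p3 <- tmp
  }
  stopifnot(inherits(p2, "two_state_params"),
            inherits(p3, "three_state_params"))
  g <- p2$r * p3$rho
  check_ergodic(g)
  2 * p3$phi1 * (1 + g) / (1 - g)
}

#' Exact lag-k autocovariance of a trend chain
#'
#' Computes \eqn{E(d_1 d_{k+1})} under the stationary law by the explicit
#' k-step transition matrix power. The closed forms \eqn{(2a-1)^k} and
#' \eqn{2\varphi_1 (b-c)^k} are equivalent; the matrix-power route serves as
#' their independent check.
#'
#' @param params a `two_state_params` or `three_state_params` object.
#' @param k positive integer lag.
#' @return The autocovariance \eqn{E(d_1 d_{k+1})}.
#' @export
autocov_exact <- function(params, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("'k' must be a single positive integer")
  Tm <- transition_matrix(params)
  states <- as.numeric(rownames(Tm))
  phi <- if (inherits(params, "two_state_params")) c(0.5, 0.5)
         else c(params$phi1, 1 - 2 * params$phi1, params$phi1)
  Tk <- diag(nrow(Tm))
  for (i in seq_len(k)) Tk <- Tk %*% Tm
  drop(t(states * phi) %*% Tk %*% states)
}

#' Simulate a stationary trend chain
#'
#' Draws a symbol sequence of length `m` from the Markov chain described by
#' `params`, started from its stationary law. Uses the R random number
#' stream, so results are reproducible under [set.seed()].
#'
#' @param m chain length.
#' @param params a `two_state_params` or `three_state_params` object.
#' @return Integer vector of trend symbols.
#' @export
simulate_trend_chain <- function(m, params) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (inherits(params, "two_state_params")) sim_chain2_cpp(m, params$a)
  else if (inherits(params, "three_state_params"))
    sim_chain3_cpp(m, params$b, params$c, params$d)
  else stop("unknown parameter class")
}

iid_cache <- new.env(parent = emptyenv())

#' Trend-chain parameters implied by an i.i.d. original series
#'
#' The TLTA comparator fixes the chain variance at the value implied by an
#' independent, identically distributed original series. For `t = 0` the
#' stay probability is exactly `a = 1/3` for any continuous marginal (of the
#' six equally likely orderings of three i.i.d. values, one of the three
#' with an initial rise continues rising). For `t > 0` the three-state
#' parameters depend on the marginal and are reproduced by Monte Carlo: a
#' length-`N` i.i.d. sample is drawn, discretized at `t`, and the transition
#' ratios counted. Results are cached per (`t`, `N`, `seed`).
#'
#' @param t trend threshold.
#' @param marginal sampling function taking a count and returning that many
#'   i.i.d. draws; standard normal by default.
#' @param N Monte-Carlo sample size for the `t > 0` case.
#' @param seed seed for the Monte-Carlo draw (isolated from the caller's RNG
#'   state).
#' @return A `two_state_params` object when `t = 0`, otherwise a
#'   `three_state_params` object.
#' @export
iid_params <- function(t = 0, marginal = stats::rnorm, N = 1e6,
                       seed = 20220426) {
  if (t == 0) return(two_state_params(1 / 3))
  if (N < 1e5)
    warning("N < 1e5: i.i.d. parameter estimates may be imprecise")
  key <- paste0("t", format(t, digits = 15), "_N", N, "_s", seed)
  if (!is.null(iid_cache[[key]])) return(iid_cache[[key]])
  res <- local_seed(seed, {
    x <- marginal(N)
    estimate_three_state(pair_counts(trend_discretize(x, t)))
  })
  iid_cache[[key]] <- res
  res
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
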