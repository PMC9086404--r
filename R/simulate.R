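#' Simulate an independent pair of stationary null series
#'
#' Generates two independent series from one of three stationary null
#' models with standard normal innovations:
#' * `"ar1"`: \eqn{X_t = \rho_1 X_{t-1} + \epsilon_t} (and likewise for Y
#'   with \eqn{\rho_2});
#' * `"arma11"`: \eqn{X_t = \rho_1 X_{t-1} + \epsilon_t +
#'   0.5\epsilon_{t-1}};
#' * `"arma11_tar1"`: X follows the ARMA(1,1) recursion while Y follows a
#'   threshold AR(1): \eqn{Y_t = \rho_2 Y_{t-1} + \epsilon_t} when
#'   \eqn{Y_{t-1} \le -1}, else \eqn{Y_t = 0.5 Y_{t-1} + \epsilon_t}.
#'
#' \eqn{X_1} and \eqn{Y_1} are standard normal; `burn_in` initial values are
#' generated and discarded so the retained `n` values are effectively drawn
#' from the stationary law. Uses the current R random stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @param model one of `"ar1"`, `"arma11"`, `"arma11_tar1"`.
#' @param rho1,rho2 autoregressive coefficients, `|rho| < 1`.
#' @param n retained series length.
#' @param burn_in discarded prefix length.
#' @return List with numeric vectors `x` and `y` of length `n`.
#' @examples
#' set.seed(1)
#' p <- simulate_null_pair("ar1", 0.5, 0.5, n = 200)
#' @export
simulate_null_pair <- function(model = c("ar1", "arma11", "arma11_tar1"),
                               rho1 = 0, rho2 = 0, n, burn_in = 100) {
  model <- match.arg(model)
  if (abs(rho1) >= 1 || abs(rho2) >= 1)
    stop("autoregressive coefficients must satisfy |rho| < 1")
  n <- as.integer(n)
  burn_in <- as.integer(burn_in)
  if (n < 2L) stop("'n' must be at least 2")
  if (burn_in < 0L) stop("'burn_in' must be non-negative")
  N <- burn_in + n
  keep <- (burn_in + 1L):N
  gen_arma <- function(rho, ma) {
    e <- rnorm(N)
    init <- rnorm(1)
    u <- e[2:N] + ma * e[1:(N - 1)]
    c(init, stats::filter(u, rho, method = "recursive", init = init))
  }
  gen_tar <- function(rho) {
    e <- rnorm(N)
    yv <- numeric(N)
    yv[1] <- rnorm(1)
    for (i in 2:N) {
      yv[i] <- if (yv[i - 1] <= -1) rho * yv[i - 1] + e[i]
               else 0.5 * yv[i - 1] + e[i]
    }
    yv
  }
  xy <- switch(model,
    ar1 = list(x = gen_arma(rho1, 0), y = gen_arma(rho2, 0)),
    arma11 = list(x = gen_arma(rho1, 0.5), y = gen_arma(rho2, 0.5)),
    arma11_tar1 = list(x = gen_arma(rho1, 0.5), y = gen_tar(rho2)))
  list(x = xy$x[keep], y = xy$y[keep])
}

#' Empirical type I error rate of an LTA significance method
#'
#' Simulates `n_reps` independent pairs from a stationary null model,
#' applies the chosen significance method to each, and reports the fraction
#' of p-values at or below `alpha`. Each replicate uses its own child seed
#' derived from `seed`, so any single replicate is reproducible in
#' isolation. Degenerate replicates (constant trend chains, more common at
#' small `n`) are counted as non-rejections and tallied in `n_degenerate`.
#'
#' @inheritParams simulate_null_pair
#' @param method `"stlta"`, `"tlta"`, `"permutation"`, or a function
#'   `f(x, y, t, D)` returning a list with a `p_value` element (useful for
#'   harness calibration).
#' @param t,D discretization threshold and maximum delay.
#' @param alpha nominal significance level.
#' @param n_reps number of simulated replicate pairs.
#' @param n_perm permutations per replicate (permutation method only).
#' @param permute permutation convention, see [lta()].
#' @param seed master seed for the experiment.
#' @return A one-row data.frame with the design, the rejection `rate`, its
#'   binomial Monte-Carlo standard error `mc_se`, and `n_degenerate`.
#' @export
type_one_error <- function(model = "ar1", rho1 = 0, rho2 = 0, n = 200,
                           method = "stlta", t = 0, D = 0, alpha = 0.05,
                           n_reps = 2000, n_perm = 1000,
                           permute = "symbols", seed = 1) {
  stopifnot(n_reps >= 1)
  child <- derive_seeds(seed, n_reps)
  is_fun <- is.function(method)
  rej <- 0L
  ndeg <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(child[r])
    pair <- simulate_null_pair(model, rho1, rho2, n)
    res <- if (is_fun) method(pair$x, pair$y, t, D)
           else lta(pair$x, pair$y, t = t, D = D, method = method,
                    n_perm = n_perm, permute = permute)
    if (isTRUE(res$degenerate)) {
      ndeg <- ndeg + 1L
    } else if (res$p_value <= alpha) {
      rej <- rej + 1L
    }
  }
  rate <- rej / n_reps
  data.frame(model = model, rho1 = rho1, rho2 = rho2, n = n, t = t, D = D,
             method = if (is_fun) "custom" else toupper(method),
             alpha = alpha, n_reps = n_reps,
             n_perm = if (identical(method, "permutation")) n_perm else NA,
             rate = rate, mc_se = sqrt(rate * (1 - rate) / n_reps),
             n_degenerate = ndeg)
}

derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

table_designs <- list(
  `1` = list(model = "ar1", t = 0), `2` = list(model = "arma11", t = 0),
  `3` = list(model = "arma11_tar1", t = 0),
  `4` = list(model = "ar1", t = 0.5),
  `5` = list(model = "arma11", t = 0.5),
  `6` = list(model = "arma11_tar1", t = 0.5))

#' Run a full type-I-error design grid
#'
#' Reproduces one of the six calibration grids: a null model (AR(1),
#' ARMA(1,1) or ARMA(1,1)-TAR(1)) crossed with threshold `t = 0` (grids
#' 1-3) or `t = 0.5` (grids 4-6), six autoregressive coefficient pairs
#' ((-0.5,-0.5), (0,0), (0.3,0.3), (0.3,0.5), (0.5,0.5), (0.5,0.8)) and six
#' sample sizes (20, 40, 60, 80, 100, 200), with delay `D = 0` and nominal
#' level 0.05. Each cell gets its own seed derived from `seed`.
#'
#' @param table_id integer 1 to 6 selecting the model/threshold design.
#' @param methods character vector of methods to run per cell.
#' @param n_reps replicates per cell (the full-fidelity experiment uses
#'   10000; the default keeps routine runs fast).
#' @param n_perm permutations per replicate for the permutation method.
#' @param seed master seed.
#' @param alpha nominal level.
#' @return A tidy data.frame with one row per (coefficient pair, n, method)
#'   cell, as in [type_one_error()].
#' @export
run_table <- function(table_id, methods = c("stlta", "tlta"),
                      n_reps = 2000, n_perm = 1000, seed = 1,
                      alpha = 0.05) {
  design <- table_designs[[as.character(table_id)]]
  if (is.null(design)) stop("'table_id' must be an integer in 1..6")
  rhos <- list(c(-0.5, -0.5), c(0, 0), c(0.3, 0.3), c(0.3, 0.5),
               c(0.5, 0.5), c(0.5, 0.8))
  ns <- c(20L, 40L, 60L, 80L, 100L, 200L)
  cells <- expand.grid(rho = seq_along(rhos), n = ns,
                       method = methods, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rr <- rhos[[cells$rho[i]]]
    out[[i]] <- type_one_error(design$model, rr[1], rr[2], cells$n[i],
                               method = cells$method[i], t = design$t,
                               D = 0, alpha = alpha, n_reps = n_reps,
                               n_perm = n_perm, seed = seeds[i])
  }
  do.call(rbind, out)
}
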