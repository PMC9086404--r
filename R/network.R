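#' Read a wide abundance table
#'
#' Expects a delimited text file with factor identifiers in the first
#' column and one column per (time-ordered) sample. Blank cells and the
#' sentinel `NA` become missing values.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @return Numeric matrix, rows = factors (rownames), columns = time
#'   points.
#' @export
read_abundance <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate factor identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(w <- as.numeric(v))
      if (any(is.na(w) & !is.na(v)))
        stop("non-numeric cell(s) in column '", names(vals)[j], "'")
      vals[[j]] <- w
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  mat
}

#' Filter factors by prevalence
#'
#' Retains factors observed (non-missing and non-zero) in at least
#' `min_fraction` of the time points, emulating the "core" factor selection
#' used before association screening.
#'
#' @param tab numeric matrix, rows = factors.
#' @param min_fraction required fraction of observed time points, in
#'   (0, 1].
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(tab, min_fraction) {
  stopifnot(is.matrix(tab), min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(tab) & tab != 0)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("prevalence filter removed every factor")
  tab[keep, , drop = FALSE]
}

#' Linearly interpolate missing values
#'
#' Fills interior missing runs linearly between the flanking observed
#' values; leading/trailing gaps are filled by the nearest observed value
#' (linear interpolation is undefined there).
#'
#' @param tab numeric matrix, rows = factors; each row must have at least 2
#'   non-missing values.
#' @return The completed matrix.
#' @examples
#' interpolate_missing(rbind(a = c(1, NA, 3), b = c(NA, 2, 3)))
#' @export
interpolate_missing <- function(tab) {
  stopifnot(is.matrix(tab))
  idx <- seq_len(ncol(tab))
  t(apply(tab, 1, function(row) {
    obs <- !is.na(row)
    if (sum(obs) < 2L)
      stop("a factor has fewer than 2 observed values; cannot interpolate")
    if (all(obs)) return(row)
    approx(idx[obs], row[obs], xout = idx, rule = 2)$y
  }))
}

#' All-pairs local trend association screening
#'
#' Applies [lta()] to every unordered pair of factors in an abundance
#' table and controls the false discovery rate by Benjamini-Hochberg over
#' the non-degenerate tests. This is the network-building step used for
#' OTU association screening: with `k` factors it performs
#' `choose(k, 2)` tests.
#'
#' @param tab numeric matrix, rows = factors with unique rownames, columns
#'   = ordered time points; no missing values (apply
#'   [interpolate_missing()] first).
#' @param method significance method passed to [lta()].
#' @param t,D discretization threshold and maximum delay.
#' @param alpha p-value threshold for calling an edge significant.
#' @param q BH-adjusted q-value threshold.
#' @param n_perm permutations per pair (permutation method only).
#' @param permute permutation convention, see [lta()].
#' @param min_prevalence optional prevalence fraction; when supplied,
#'   [prevalence_filter()] is applied first.
#' @param interpolate fill missing values by [interpolate_missing()]
#'   before testing.
#' @param strict strict threshold inequalities in the discretization.
#' @return A data.frame with one row per unordered factor pair
#'   (`factor_a < factor_b` lexicographically): score, alignment, `sigma`,
#'   `state_model`, `p_value`, `q_value`, `degenerate` and `significant`
#'   (p <= alpha and q <= q).
#' @export
lta_network <- function(tab, method = "stlta", t = 0, D = 3,
                        alpha = 0.05, q = 0.05, n_perm = 1000,
                        permute = "symbols", min_prevalence = NULL,
                        interpolate = TRUE, strict = FALSE) {
  stopifnot(is.matrix(tab))
  if (is.null(rownames(tab)) || anyDuplicated(rownames(tab)))
    stop("'tab' must have unique rownames identifying the factors")
  if (nrow(tab) < 2L) stop("need at least 2 factors")
  if (!is.null(min_prevalence))
    tab <- prevalence_filter(tab, min_prevalence)
  if (interpolate && anyNA(tab)) tab <- interpolate_missing(tab)
  if (anyNA(tab))
    stop("missing values present; set 'interpolate = TRUE'")
  ids <- rownames(tab)
  ord <- order(ids)
  tab <- tab[ord, , drop = FALSE]
  ids <- ids[ord]
  k <- length(ids)
  pairs <- utils::combn(k, 2)
  res <- vector("list", ncol(pairs))
  for (e in seq_len(ncol(pairs))) {
    i <- pairs[1, e]; j <- pairs[2, e]
    fit <- lta(tab[i, ], tab[j, ], t = t, D = D, method = method,
               n_perm = n_perm, permute = permute, strict = strict)
    res[[e]] <- data.frame(
      factor_a = ids[i], factor_b = ids[j], score = fit$score,
      start_a = fit$alignment$start_x, start_b = fit$alignment$start_y,
      length = fit$alignment$length, t = t, D = D,
      method = fit$method, state_model = fit$state_model,
      sigma = fit$sigma, p_value = fit$p_value,
      degenerate = fit$degenerate, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, res)
  edges$q_value <- NA_real_
  ok <- !edges$degenerate & !is.na(edges$p_value)
  edges$q_value[ok] <- p.adjust(edges$p_value[ok], method = "BH")
  edges$significant <- ok & edges$p_value <= alpha &
    edges$q_value <= q
  edges
}

#' Simulate a synthetic wide abundance table
#'
#' Generates AR(1)-autocorrelated latent series (standard normal
#' innovations), exponentiated to abundance scale, with optional planted
#' co-trending pairs and missing values. Planted pairs share innovation
#' signs: factor `2i` reuses the signs of factor `2i - 1`'s innovations
#' with its own magnitudes, so the pair co-trends without being identical.
#' A stand-in for real OTU tables in examples and tests (it does not
#' emulate compositionality, zero inflation or sequencing noise).
#'
#' @param n_factors number of factors (rows).
#' @param n_time number of time points.
#' @param planted_pairs number of co-trending pairs to plant (factors
#'   1-2, 3-4, ...).
#' @param autocorr AR(1) coefficient of the latent series.
#' @param missing_rate fraction of cells set to `NA` at random.
#' @param seed seed; when non-NULL the table is reproducible.
#' @return Numeric matrix with rownames `F001, F002, ...`.
#' @export
simulate_abundance_table <- function(n_factors, n_time,
                                     planted_pairs = 0, autocorr = 0.5,
                                     missing_rate = 0, seed = NULL) {
  stopifnot(n_factors >= 1, n_time >= 3, abs(autocorr) < 1,
            planted_pairs >= 0, 2 * planted_pairs <= n_factors,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  burn <- 50L
  N <- n_time + burn
  innov <- matrix(rnorm(n_factors * N), n_factors, N)
  for (p in seq_len(planted_pairs)) {
    i <- 2L * p - 1L
    innov[i + 1L, ] <- sign(innov[i, ]) * abs(innov[i + 1L, ])
  }
  lat <- t(apply(innov, 1, function(e)
    as.numeric(stats::filter(e, autocorr, method = "recursive"))))
  lat <- lat[, (burn + 1L):N, drop = FALSE]
  tab <- exp(lat)
  if (missing_rate > 0)
    tab[runif(length(tab)) < missing_rate] <- NA
  rownames(tab) <- sprintf("F%03d", seq_len(n_factors))
  colnames(tab) <- sprintf("t%d", seq_len(n_time))
  tab
}
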