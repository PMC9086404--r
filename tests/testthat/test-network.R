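write_fixture <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  write.table(df, path, sep = if (ext == "csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  path
}

test_that("abundance tables round-trip through the reader", {
  df <- data.frame(otu = c("A", "B", "C"),
                   t1 = c(1, 0, 5), t2 = c(2, 1, NA), t3 = c(3, 0, 2),
                   t4 = c(4, 2, 2), t5 = c(5, 0, 1))
  tab <- read_abundance(write_fixture(df))
  expect_equal(dim(tab), c(3L, 5L))
  expect_equal(rownames(tab), c("A", "B", "C"))
  expect_true(is.na(tab["C", "t2"]))
  expect_equal(tab["A", ], c(t1 = 1, t2 = 2, t3 = 3, t4 = 4, t5 = 5))
  # csv detection by extension
  tab2 <- read_abundance(write_fixture(df, "csv"))
  expect_equal(tab2, tab)
})

test_that("the reader rejects malformed tables", {
  dup <- data.frame(otu = c("A", "A"), t1 = c(1, 2), t2 = c(3, 4))
  expect_error(read_abundance(write_fixture(dup)), "duplicate")
  bad <- data.frame(otu = c("A", "B"), t1 = c("x", "2"), t2 = c(3, 4))
  expect_error(read_abundance(write_fixture(bad)), "non-numeric")
})

test_that("prevalence filter keeps exactly the sufficiently observed factors", {
  tab <- rbind(full = rep(1, 10),
               sixty = c(rep(2, 6), rep(0, 4)),
               forty = c(rep(3, 4), rep(0, 6)),
               gappy = c(rep(4, 4), rep(NA, 6)))
  expect_equal(rownames(prevalence_filter(tab, 0.5)), c("full", "sixty"))
  expect_equal(rownames(prevalence_filter(tab, 0.6)), c("full", "sixty"))
  expect_equal(rownames(prevalence_filter(tab, 0.61)), "full")
  # threshold near zero is the identity
  expect_equal(prevalence_filter(tab, 1e-9), tab)
  expect_error(prevalence_filter(tab, 1.0001), "min_fraction")
  expect_error(prevalence_filter(tab[3, , drop = FALSE], 0.9),
               "every factor")
})

test_that("missing values are interpolated linearly, extended at the ends", {
  tab <- rbind(a = c(1, NA, 3),
               c = c(NA, 2, 3))
  out <- interpolate_missing(tab)
  expect_equal(unname(out["a", ]), c(1, 2, 3))
  expect_equal(unname(out["c", ]), c(2, 2, 3))
  run2 <- interpolate_missing(rbind(x = c(1, NA, NA, 4)))
  expect_equal(unname(run2[1, ]), c(1, 2, 3, 4))
  expect_error(interpolate_missing(rbind(x = c(NA, NA, 1))),
               "fewer than 2")
})

test_that("all-pairs screening emits one record per unordered pair", {
  tab <- simulate_abundance_table(8, 40, seed = 61)
  edges <- lta_network(tab, t = 0, D = 1)
  expect_equal(nrow(edges), choose(8, 2))
  expect_true(all(edges$factor_a < edges$factor_b))
  # invariant to input row order (up to record ordering)
  edges2 <- lta_network(tab[sample(8), ], t = 0, D = 1)
  key <- function(e) e[order(e$factor_a, e$factor_b),
                       c("factor_a", "factor_b", "score", "p_value")]
  expect_equal(key(edges2), key(edges), ignore_attr = TRUE)
})

test_that("q-values follow Benjamini-Hochberg step-up", {
  tab <- simulate_abundance_table(7, 50, seed = 62)
  edges <- lta_network(tab, t = 0.5, D = 2)
  ok <- !edges$degenerate
  expect_equal(edges$q_value[ok], bh_reference(edges$p_value[ok]))
  # hand-checked example
  expect_equal(bh_reference(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(63)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_reference(p))
  }
})

test_that("a planted co-trending pair is recovered", {
  tab <- simulate_abundance_table(6, 300, planted_pairs = 1, seed = 64)
  edges <- lta_network(tab, t = 0, D = 0)
  best <- edges[which.min(edges$p_value), ]
  expect_equal(c(best$factor_a, best$factor_b), c("F001", "F002"))
  # planted edge beats the median null edge across seeds
  hits <- 0L
  for (s in 1:20) {
    tab <- simulate_abundance_table(6, 300, planted_pairs = 1, seed = s)
    edges <- lta_network(tab, t = 0, D = 0)
    planted <- edges$factor_a == "F001" & edges$factor_b == "F002"
    if (edges$p_value[planted] <= median(edges$p_value[!planted]))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("synthetic tables honour their generation switches", {
  tab <- simulate_abundance_table(5, 30, missing_rate = 0, seed = 65)
  expect_false(anyNA(tab))
  expect_true(all(tab > 0))
  tab1 <- simulate_abundance_table(5, 30, missing_rate = 0.2, seed = 66)
  tab2 <- simulate_abundance_table(5, 30, missing_rate = 0.2, seed = 66)
  expect_identical(tab1, tab2)
  expect_gt(sum(is.na(tab1)), 0)
  # missingness then interpolation feeds cleanly into screening
  edges <- lta_network(tab1, t = 0.5, D = 1, min_prevalence = 0.3,
                       interpolate = TRUE)
  expect_true(all(!is.na(edges$p_value) | edges$degenerate))
})
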