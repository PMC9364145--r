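test_that("the inflammatory TF panel has the three families and 21 members", {
  panel <- build_inflammatory_panel()
  expect_equal(nrow(panel), 21L)
  expect_setequal(unique(panel$family), c("NF-kB", "IRF", "STAT"))
  expect_true("STAT2" %in% panel$symbol)
  expect_equal(panel$family[panel$symbol == "STAT2"], "STAT")
  expect_equal(sum(panel$family == "IRF"), 9L)
  expect_false("CD274" %in% panel$symbol)
  expect_false(anyDuplicated(panel$symbol) > 0)
})

test_that("correlate matches the closed-form product-moment oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 8)
  # independent closed-form evaluation from raw sums
  n <- 4
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_oracle), n - 2)
  rec <- correlate(x, y, "pearson")
  expect_equal(rec$r, r_oracle, tolerance = 1e-12)
  expect_equal(rec$p, p_oracle, tolerance = 1e-12)
  expect_equal(rec$n, 4L)

  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(correlate(c(1, 2, 3), c(3, 2, 1))$p, 0)
})

test_that("spearman is pearson on average ranks", {
  set.seed(3)
  x <- rnorm(20)
  y <- x^3 + rnorm(20, sd = 0.1)  # monotone, nonlinear
  sp <- correlate(x, y, "spearman")
  expect_equal(sp$r, correlate(rank(x), rank(y), "pearson")$r)
  expect_equal(sp$r, cor(x, y, method = "spearman"))
})

test_that("degenerate correlation inputs are flagged or rejected", {
  expect_error(correlate(1:5, 1:4), "equal length")
  expect_error(correlate(1:2, 2:1), "n >= 3")
  expect_error(correlate(c(1, NA, 3), c(1, 2, 3)), "finite")
  rec <- correlate(rep(1, 10), rnorm(10))
  expect_false(rec$ok)
  expect_true(is.na(rec$r))
})

test_that("bh_fdr equals the brute-force step-up oracle", {
  # frozen worked example: q = (0.04, 0.04, 0.04, 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))  # step-up collapses
  expect_equal(bh_fdr(0.3), 0.3)                    # m = 1
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))  # min over the tail
    }
    q
  }
  set.seed(5)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))  # independent cross-check
    expect_true(all(bh_fdr(p) >= p))
  }
})

test_that("screen_tfs recovers the planted regulator on the spec cohort", {
  co <- generate_cohort(synthetic_truth(seed = 7), fast_config())
  scr <- screen_tfs(co$expr, acc_from_cohort(co), build_inflammatory_panel(),
                    "CD274")
  expect_equal(scr$summary$tf[1], "STAT2")
  expect_true(scr$summary$candidate[1])
  expect_gt(scr$summary$r_region[1], 0.4)
  # q-values never undercut p-values
  expect_true(all(scr$records$q >= scr$records$p, na.rm = TRUE))
  # one record per (TF, region)
  expect_equal(nrow(scr$records), 21 * 1)
})

test_that("screen ranking is invariant to row and sample permutations", {
  co <- generate_cohort(synthetic_truth(seed = 12), fast_config())
  acc <- acc_from_cohort(co)
  base <- screen_tfs(co$expr, acc, build_inflammatory_panel(), "CD274")
  set.seed(1)
  expr_perm <- co$expr[sample(nrow(co$expr)), sample(ncol(co$expr))]
  perm <- screen_tfs(expr_perm, acc, build_inflammatory_panel(), "CD274")
  expect_equal(perm$summary$tf, base$summary$tf)
  expect_equal(perm$summary$r_region, base$summary$r_region)
})

test_that("a constant TF column is excluded but the screen continues", {
  co <- generate_cohort(synthetic_truth(seed = 2), fast_config())
  co$expr["IRF5", ] <- 3.14
  scr <- screen_tfs(co$expr, acc_from_cohort(co), build_inflammatory_panel(),
                    "CD274")
  row <- scr$summary[scr$summary$tf == "IRF5", ]
  expect_false(row$candidate)
  expect_true(is.na(row$r_region))
  expect_equal(row$rank, 21L)  # degenerate rows sink to the bottom
  flagged <- scr$records[scr$records$feature_a == "IRF5", ]
  expect_false(any(flagged$ok))
})

test_that("screen preconditions are enforced", {
  co <- generate_cohort(synthetic_truth(seed = 2), fast_config())
  acc <- acc_from_cohort(co)
  expect_error(screen_tfs(co$expr, acc, build_inflammatory_panel(), "NOPE"),
               "target gene")
  colnames(co$expr) <- paste0("X", colnames(co$expr))
  expect_error(screen_tfs(co$expr, acc, build_inflammatory_panel(), "CD274"),
               "share")
  # panel members absent from the matrix are reported, not fatal
  co2 <- generate_cohort(synthetic_truth(seed = 2), fast_config())
  expr2 <- co2$expr[setdiff(rownames(co2$expr), "IRF3"), ]
  scr <- screen_tfs(expr2, acc_from_cohort(co2), build_inflammatory_panel(),
                    "CD274")
  expect_equal(scr$missing, "IRF3")
  expect_equal(nrow(scr$summary), 20L)
})

test_that("require_all_regions gates candidates over every region", {
  co <- generate_cohort(synthetic_truth(seed = 4), fast_config())
  # two regions: the true promoter signal and an unrelated noise region
  gr <- GRanges("chrP", IRanges(c(1, 1001), width = 500))
  set.seed(99)
  vals <- rbind(co$accessibility, rnorm(length(co$accessibility)))
  acc2 <- accessibility_matrix(gr, matrix(vals, nrow = 2,
                                          dimnames = list(NULL, colnames(co$expr))),
                               "log2")
  strict <- screen_tfs(co$expr, acc2, build_inflammatory_panel(), "CD274",
                       screen_config(require_all_regions = TRUE))
  loose <- screen_tfs(co$expr, acc2, build_inflammatory_panel(), "CD274",
                      screen_config(require_all_regions = FALSE))
  expect_true(sum(strict$summary$candidate) <= sum(loose$summary$candidate))
  expect_true(loose$summary$candidate[loose$summary$tf == "STAT2"])
})
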