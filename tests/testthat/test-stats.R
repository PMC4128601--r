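# paired directional and equivalence tests, battery orchestration

test_that("paired inequality test matches the closed-form t computation", {
  set.seed(21)
  a <- rnorm(8, 0.1); b <- rnorm(8)
  res <- paired_inequality_test(a, b, direction = 1)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  expect_equal(res$p, pt(tstat, df = 7, lower.tail = FALSE), tolerance = 1e-10)
  # flipping direction complements the one-tailed p
  res2 <- paired_inequality_test(a, b, direction = -1)
  expect_equal(res2$p, 1 - res$p, tolerance = 1e-10)
  # all-zero differences give the symmetric p = 0.5
  expect_equal(paired_inequality_test(a, a, 1)$p, 0.5)
  expect_error(paired_inequality_test(1, 2, 1), "n >= 2")
})

test_that("TOST equivalence confirms and refuses per its design", {
  set.seed(22)
  # identical vectors with spread across subjects: decisively equivalent
  a <- rnorm(8, 0.5, 0.1)
  expect_lt(paired_equivalence_test(a, a, margin = 0.03)$p, 0.05)
  # tight noise below margin/2: confirmed at n = 8
  b <- a + rnorm(8, 0, 0.01)
  expect_lt(paired_equivalence_test(a, b, margin = 0.03)$p, 0.05)
  # true difference 2x margin, SD margin/4: not confirmed
  margin <- 0.03
  d <- a + 2 * margin + rnorm(8, 0, margin / 4)
  expect_gt(paired_equivalence_test(a, d, margin = margin)$p, 0.05)
  # the relative margin resolves against the grand mean
  va <- rnorm(8, 100, 1); vb <- va + rnorm(8, 0, 1)
  r1 <- paired_equivalence_test(va, vb, margin = 0.10, margin_type = "relative")
  expect_equal(r1$margin, 0.10 * mean(c(mean(va), mean(vb))), tolerance = 1e-10)
  expect_error(paired_equivalence_test(a, b, margin = -0.1),
               "configuration error")
})

test_that("equivalence never confirms a true difference beyond the margin as SD -> 0", {
  a <- rep(1, 8)
  b <- rep(1 + 0.06, 8)       # difference 2x the 0.03 margin, zero variance
  res <- paired_equivalence_test(a, b, margin = 0.03)
  expect_equal(res$p, 1)
  expect_false(res$pass)
})

test_that("the battery runs all hypotheses per algorithm and checks completeness", {
  set.seed(23)
  conds <- c("Z21a", "P21a", "Z100", "P100", "Z21b", "P21b")
  grid <- expand.grid(subject = 1:8, condition = conds,
                      algorithm = c("A0", "I3"), stringsAsFactors = FALSE)
  grid$vt <- 10 + rnorm(nrow(grid), 0, 0.1)
  grid$cov <- rnorm(nrow(grid), 0, 0.01) +
    ifelse(grid$condition %in% c("P21a", "P21b"), -0.05, 0) +
    ifelse(grid$condition == "Z100", 0.08, 0)
  bat <- run_battery(grid)
  expect_s3_class(bat, "eit_battery")
  expect_equal(nrow(bat), 12 * 2)
  expect_true(all(bat$p >= 0 & bat$p <= 1))
  expect_true(all(bat$n == 8))
  expect_true(all(is.finite(bat$wilcoxon_p)))
  # this constructed ensemble: V_T equivalences pass, CoV effects as built
  sub <- bat[bat$algorithm == "A0", ]
  expect_true(all(sub$pass[grepl("^VT", sub$id)]))
  expect_true(sub$pass[sub$id == "CoV_P21_lt_Z21"])
  expect_true(sub$pass[sub$id == "CoV_Z100_gt_Z21"])
  # grid rendering: hypotheses x algorithms
  g <- battery_grid(bat)
  expect_equal(dim(g), c(12, 3))
  expect_named(g, c("id", "A0", "I3"))
  # missing cells are reported by name
  expect_error(run_battery(grid[-1, ]), "missing.*subject")
})

test_that("a null ensemble fails inequalities and passes equivalences", {
  set.seed(24)
  conds <- c("Z21a", "P21a", "Z100", "P100", "Z21b", "P21b")
  grid <- expand.grid(subject = 1:8, condition = conds,
                      algorithm = "A0", stringsAsFactors = FALSE)
  grid$vt <- 10 + rnorm(nrow(grid), 0, 0.05)   # tight noise, no effects
  grid$cov <- rnorm(nrow(grid), 0, 0.003)
  bat <- run_battery(grid)
  expect_true(all(bat$pass[bat$kind == "equivalence"]))
  expect_false(any(bat$pass[bat$kind == "inequality"]))
})
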