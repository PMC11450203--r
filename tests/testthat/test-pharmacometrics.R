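test_that("percent inhibition spans the control anchors and stays affine-invariant", {
  expect_equal(percent_inhibition(1000, 1000, 0), 0)
  expect_equal(percent_inhibition(0, 1000, 0), 100)
  expect_equal(percent_inhibition(250, 1000, 0), 75)
  # over-killing beyond the positive control is reported, not clipped
  expect_gt(percent_inhibition(-50, 1000, 0), 100)
  # rescaling all luminescence values by c > 0 changes nothing
  expect_equal(percent_inhibition(250 * 7.3, 1000 * 7.3, 0), 75)
  expect_equal(percent_inhibition(400 * 0.2, 1000 * 0.2, 100 * 0.2),
               percent_inhibition(400, 1000, 100))
  expect_error(percent_inhibition(10, 100, 100), "DegenerateControls")
  expect_error(percent_inhibition(10, 50, 100), "DegenerateControls")
})

test_that("noise-free 4PL data round-trips through the fit within 1%", {
  doses <- c(0, 10^seq(-3, 1, length.out = 8))
  for (p in list(c(bottom = 0, top = 85, ec50 = 0.05, slope = 1.2),
                 c(bottom = 5, top = 95, ec50 = 0.5, slope = 2.4),
                 c(bottom = -2, top = 70, ec50 = 0.02, slope = 0.8))) {
    y <- p["bottom"] + (p["top"] - p["bottom"]) /
      (1 + (p["ec50"] / doses)^p["slope"])
    fit <- fit_hill(doses, y)
    expect_false(fit$fallback)
    expect_lt(abs(fit$ec50_uM - p["ec50"]) / p["ec50"], 0.01)
    expect_lt(abs(fit$slope - p["slope"]) / p["slope"], 0.01)
    expect_lt(abs(fit$top - p["top"]) / max(abs(p["top"]), 1), 0.01)
  }
})

test_that("degenerate dose-response inputs are handled explicitly", {
  expect_error(fit_hill(c(0.1, 1), c(10, 60)), ">= 3")
  flat <- fit_hill(c(0, 0.1, 1, 10), rep(42, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$bottom, 42)
  expect_equal(predict(flat, c(0, 5)), c(42, 42))
})

test_that("ZIP is zero for Bliss-consistent surfaces and recovers planted excess", {
  doses <- c(0, 0.1, 0.5, 2.5)
  f1 <- hill_inhibition(doses, 0.3, 1.4, 90) / 100
  f2 <- hill_inhibition(doses, 0.8, 1.0, 70) / 100
  bliss <- outer(f1, f2, function(a, b) a + b - a * b) * 100
  expect_lt(abs(as.numeric(zip_score(dose_response_matrix(doses, doses, bliss)))), 0.5)
  planted <- bliss
  planted[-1, -1] <- planted[-1, -1] + 10
  expect_equal(as.numeric(zip_score(dose_response_matrix(doses, doses, planted))), 10,
               tolerance = 0.05)
  # all-zero matrix scores zero
  zero <- matrix(0, 4, 4)
  expect_equal(abs(as.numeric(zip_score(dose_response_matrix(doses, doses, zero)))), 0,
               tolerance = 1e-9)
})

test_that("ZIP hand oracle: margins at 50% with observed 85% gives 10", {
  # single interior cell: Bliss expectation 0.5 + 0.5 - 0.25 = 0.75,
  # observed 0.85 -> delta 0.10 -> ZIP 10 (two-point margins used raw)
  grid <- outer(c(0, 0.5), c(0, 0.5), function(a, b) a + b - a * b) * 100
  grid[2, 2] <- 85
  z <- zip_score(dose_response_matrix(c(0, 1), c(0, 1), grid))
  expect_equal(as.numeric(z), 10, tolerance = 1e-9)
})

test_that("dose region restricts the ZIP average to the requested window", {
  doses <- c(0, 0.1, 1, 10)
  f1 <- hill_inhibition(doses, 0.5, 1, 80) / 100
  bliss <- outer(f1, f1, function(a, b) a + b - a * b) * 100
  planted <- bliss
  planted[4, 4] <- planted[4, 4] + 20  # excess only at the top corner
  full <- as.numeric(zip_score(dose_response_matrix(doses, doses, planted)))
  corner <- as.numeric(zip_score(
    dose_response_matrix(doses, doses, planted),
    region = list(drug_a = c(5, 10), drug_b = c(5, 10))))
  expect_equal(corner, 20, tolerance = 0.5)
  expect_lt(full, corner)
})

test_that("DSS matches its anchors and a fine-grid quadrature oracle", {
  flat100 <- fit_hill(c(0, 0.01, 0.1, 1, 10), rep(100, 5))
  expect_equal(dss(flat100, c(0.01, 10)), 100, tolerance = 1e-6)
  flat_thr <- fit_hill(c(0, 0.01, 0.1, 1, 10), rep(10, 5))
  expect_equal(dss(flat_thr, c(0.01, 10)), 0, tolerance = 1e-9)
  # mid-sigmoid curve vs trapezoidal integration on a 10x finer grid
  doses <- c(0, 10^seq(-3, 1, length.out = 9))
  y <- hill_inhibition(doses, 0.1, 1.3, 80)
  fit <- fit_hill(doses, y)
  rng <- c(0.001, 10)
  grid <- seq(log10(rng[1]), log10(rng[2]), length.out = 901)
  vals <- pmax(0, predict(fit, 10^grid) - 10)
  trap <- sum((vals[-1] + vals[-length(vals)]) / 2 * diff(grid))
  oracle <- 100 * trap / ((100 - 10) * diff(log10(rng)))
  expect_equal(dss(fit, rng), oracle, tolerance = 0.5)
  expect_error(dss(fit, c(10, 0.1)), "InvalidRange")
})

test_that("DSS is monotone under pointwise dominance", {
  doses <- c(0, 10^seq(-2, 1, length.out = 6))
  lo <- fit_hill(doses, hill_inhibition(doses, 0.5, 1.2, 60))
  hi <- fit_hill(doses, hill_inhibition(doses, 0.2, 1.2, 90))
  expect_gt(dss(hi, c(0.01, 10)), dss(lo, c(0.01, 10)))
})

test_that("AUC equals brute-force pair counting and survives monotone maps", {
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  scores <- c(3.2, 1.1, 2.0, 2.0, 0.5, 1.1)
  brute <- function(l, s) {
    pos <- s[l]; neg <- s[!l]
    pairs <- expand.grid(p = pos, n = neg)
    mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n, 0.5, 0)))
  }
  expect_equal(roc_auc(labels, scores), brute(labels, scores))
  set.seed(8)
  for (i in 1:5) {
    l <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(l)) < 2) next
    s <- rnorm(30)
    expect_equal(roc_auc(l, s), brute(l, s))
    expect_equal(roc_auc(l, exp(2 * s) + 5), roc_auc(l, s))
  }
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(5, 4, 1)), 1.0)
  expect_error(roc_auc(c(TRUE, TRUE), c(1, 2)), "OneClassOnly")
})

test_that("DeLong test is null for identical scores and flags separations", {
  set.seed(4)
  l <- rep(c(TRUE, FALSE), each = 40)
  s <- rnorm(80) + l
  same <- delong_test(l, s, s)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  better <- as.numeric(l) * 3 + rnorm(80, sd = 0.3)
  worse <- rnorm(80)
  dt <- delong_test(l, better, worse)
  expect_lt(dt$p, 0.01)
  expect_gt(dt$auc1, dt$auc2)
})

test_that("dose matrices round-trip through the CSV layout", {
  doses <- c(0, 0.1, 1, 10)
  grid <- outer(hill_inhibition(doses, 0.5, 1, 80) / 100,
                hill_inhibition(doses, 1, 1.5, 60) / 100,
                function(a, b) a + b - a * b) * 100
  mat <- dose_response_matrix(doses, doses, grid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_matrix(mat, path)
  back <- read_dose_matrix(path)
  expect_equal(back$row_doses, mat$row_doses)
  expect_equal(back$inhibition, mat$inhibition, ignore_attr = TRUE)
  expect_error(dose_response_matrix(c(0.1, 1), c(0, 1), grid[1:2, 1:2]),
               "margins")
})
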