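test_that("model fitting rejects undersized or under-grouped tables", {
  tab <- tiny_training_table()
  small <- tab[1:50, ]
  attributes(small)[c("landmark_genes", "fp_bits")] <-
    attributes(tab)[c("landmark_genes", "fp_bits")]
  class(small) <- class(tab)
  expect_error(fit_inhibition_model(small), "InsufficientData")
  expect_error(
    fit_inhibition_model(tab, cv = list(repeats = 1L, folds = 1000L)),
    "groups")
})

test_that("a constant-target table yields constant predictions with ~zero CV RMSE", {
  tab <- constant_table(50)
  m <- fit_inhibition_model(tab, cv = list(repeats = 2L, folds = 5L),
                            n_search = 1L, grid = tiny_grid(), seed = 3L)
  expect_lt(m$cv_rmse, 1e-6)
  ref <- tiny_reference()
  sig <- stats::setNames(rnorm(length(m$landmark_genes), 0, 0.5),
                         m$landmark_genes)
  rec <- predict_inhibition(m, sig, ref$fingerprints, dose_grid = c(0.1, 1))
  expect_equal(rec$predicted_inhibition_pct, rep(50, nrow(rec)),
               tolerance = 1e-6)
  expect_lt(rec$halfwidth[1], 1e-6)
  expect_gt(rec$confidence[1], 1 - 1e-6)
})

test_that("fitting is deterministic under a fixed seed", {
  tab <- tiny_training_table()
  m1 <- fit_inhibition_model(tab, cv = list(repeats = 1L, folds = 4L),
                             n_search = 2L, grid = tiny_grid(), seed = 5L)
  m2 <- fit_inhibition_model(tab, cv = list(repeats = 1L, folds = 4L),
                             n_search = 2L, grid = tiny_grid(), seed = 5L)
  expect_identical(sort(m1$calibration_residuals),
                   sort(m2$calibration_residuals))
  expect_identical(m1$hyperparameters, m2$hyperparameters)
})

test_that("prediction invariance to training-row order under fixed seed", {
  tab <- tiny_training_table()
  set.seed(99)
  perm <- sample.int(nrow(tab))
  shuffled <- tab[perm, ]
  attributes(shuffled)[c("landmark_genes", "fp_bits")] <-
    attributes(tab)[c("landmark_genes", "fp_bits")]
  class(shuffled) <- class(tab)
  # build_training_table sorts rows; emulate by restoring the sort
  shuffled <- shuffled[order(shuffled$drug_id, shuffled$cell_line_id,
                             shuffled$dose_uM), ]
  m1 <- fit_inhibition_model(tab, cv = list(repeats = 1L, folds = 4L),
                             n_search = 1L, grid = tiny_grid(), seed = 2L)
  m2 <- fit_inhibition_model(shuffled, cv = list(repeats = 1L, folds = 4L),
                             n_search = 1L, grid = tiny_grid(), seed = 2L)
  ref <- tiny_reference()
  sig <- stats::setNames(rep(0.3, length(m1$landmark_genes)),
                         m1$landmark_genes)
  p1 <- predict_inhibition(m1, sig, ref$fingerprints, 0.5)
  p2 <- predict_inhibition(m2, sig, ref$fingerprints, 0.5)
  expect_equal(p1$predicted_inhibition_pct, p2$predicted_inhibition_pct)
})

test_that("prediction enforces the feature schema and grid shape", {
  m <- tiny_model()
  ref <- tiny_reference()
  sig <- stats::setNames(numeric(length(m$landmark_genes)) + 0.1,
                         m$landmark_genes)
  bad_fp <- ref$fingerprints[, 1:10]
  expect_error(predict_inhibition(m, sig, bad_fp, 0.5), "SchemaMismatch")
  expect_error(predict_inhibition(m, rep(0.1, 7), ref$fingerprints, 0.5),
               "SchemaMismatch")
  # one dose -> exactly one record per drug
  rec <- predict_inhibition(m, sig, ref$fingerprints, dose_grid = 0.5)
  expect_equal(nrow(rec), nrow(ref$fingerprints))
  expect_true(all(rec$predicted_inhibition_pct >= 0 &
                    rec$predicted_inhibition_pct <= 100))
  # unknown signature genes are dropped, missing imputed to zero
  rec2 <- predict_inhibition(m, c(NOT_A_GENE = 5), ref$fingerprints, 0.5)
  rec3 <- predict_inhibition(
    m, stats::setNames(numeric(length(m$landmark_genes)), m$landmark_genes),
    ref$fingerprints, 0.5)
  expect_equal(rec2$predicted_inhibition_pct, rec3$predicted_inhibition_pct)
})

test_that("conformal filter keeps the boundary and preserves order", {
  rec <- data.frame(drug_id = c("a", "b", "c"),
                    confidence = c(0.79, 0.80, 0.95))
  kept <- conformal_filter(rec, 0.8)
  expect_equal(kept$drug_id, c("b", "c"))
  all_conf <- data.frame(drug_id = letters[1:4], confidence = rep(1, 4))
  expect_equal(nrow(conformal_filter(all_conf, 0.8)), 4L)
  expect_equal(nrow(conformal_filter(rec, 0.999)), 0L)
})

test_that("dose cap is boundary-inclusive and warns when nothing survives", {
  rec <- data.frame(drug_id = "a", dose_uM = c(0.1, 1.0, 3.0))
  expect_equal(apply_dose_cap(rec, 1.0)$dose_uM, c(0.1, 1.0))
  expect_equal(nrow(apply_dose_cap(rec, Inf)), 3L)
  expect_warning(out <- apply_dose_cap(rec, 0.01), "exceed")
  expect_equal(nrow(out), 0L)
})

test_that("split-conformal half-width uses the order-statistic quantile", {
  res <- 1:99
  # ceiling((99 + 1) * 0.9) = 90th order statistic
  expect_equal(conformal_halfwidth(res, 0.9), 90)
  expect_equal(conformal_halfwidth(c(5), 0.9), 5)
})

test_that("models survive a save/load round trip", {
  m <- tiny_model()
  dir <- withr::local_tempdir()
  save_inhibition_model(m, dir)
  m2 <- load_inhibition_model(dir)
  ref <- tiny_reference()
  sig <- stats::setNames(rep(0.2, length(m$landmark_genes)),
                         m$landmark_genes)
  p1 <- predict_inhibition(m, sig, ref$fingerprints, c(0.1, 1))
  p2 <- predict_inhibition(m2, sig, ref$fingerprints, c(0.1, 1))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("permuting targets destroys held-out association (leakage guard)", {
  tab <- tiny_training_table()
  hold <- tab$cell_line_id %in% c("C007", "C008")
  train <- tab[!hold, ]
  attributes(train)[c("landmark_genes", "fp_bits")] <-
    attributes(tab)[c("landmark_genes", "fp_bits")]
  class(train) <- class(tab)
  perm <- train
  set.seed(1)
  perm$inhibition_pct <- sample(perm$inhibition_pct)
  fit_real <- fit_inhibition_model(train, cv = list(repeats = 1L, folds = 4L),
                                   n_search = 1L, grid = tiny_grid(), seed = 1L)
  fit_perm <- fit_inhibition_model(perm, cv = list(repeats = 1L, folds = 4L),
                                   n_search = 1L, grid = tiny_grid(), seed = 1L)
  ho <- tab[hold, ]
  x_sig <- as.matrix(ho[, attr(tab, "landmark_genes")])
  rho <- function(m) {
    preds <- vapply(seq_len(nrow(ho)), function(i) {
      predict_inhibition(
        m, stats::setNames(x_sig[i, ], colnames(x_sig)),
        ho[i, attr(tab, "fp_bits"), drop = FALSE], ho$dose_uM[i]
      )$predicted_inhibition_pct
    }, numeric(1))
    stats::cor(preds, ho$inhibition_pct, method = "spearman")
  }
  expect_gt(rho(fit_real), 0.5)
  expect_lt(abs(rho(fit_perm)), 0.25)
})
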