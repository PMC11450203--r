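# Feature matrix in the fixed schema: landmark signature, fingerprint bits,
# log10 dose. Used for both training and prediction.
feature_matrix <- function(sig_mat, fp_mat, log10_dose) {
  cbind(sig_mat, fp_mat, log10_dose = log10_dose)
}

# Grouped fold assignment: all rows of one (drug, cell line) pair share a
# fold, limiting leakage of near-duplicate signatures across folds.
grouped_folds <- function(groups, k) {
  ug <- unique(groups)
  fold_of_group <- sample(rep_len(seq_len(k), length(ug)))
  fold_of_group[match(groups, ug)]
}

default_search_grid <- function() {
  list(
    nrounds = c(100L, 200L),
    max_depth = c(4L, 6L),
    eta = c(0.1, 0.3),
    min_child_weight = c(1, 5, 20),
    colsample_bytree = c(0.5, 0.8),
    subsample = c(0.8, 1)
  )
}

xgb_fit <- function(x, y, hp, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror",
      max_depth = hp$max_depth,
      eta = hp$eta,
      min_child_weight = hp$min_child_weight,
      colsample_bytree = hp$colsample_bytree,
      subsample = hp$subsample,
      tree_method = "hist",
      nthread = 1,
      seed = seed
    ),
    data = dtrain,
    nrounds = hp$nrounds,
    verbose = 0
  )
}

#' Fit the dose-aware inhibition regressor
#'
#' Gradient-boosted tree regression of percent inhibition on
#' (landmark signature, fingerprint, log10 dose). Hyperparameters are
#' selected by randomized search (`n_search` draws from a documented grid)
#' scored by grouped cross-validated RMSE on a `search_folds`-fold
#' screening split; the chosen configuration is then assessed by repeated
#' grouped cross-validation (`cv$repeats` x `cv$folds`), whose pooled
#' out-of-fold absolute residuals become the conformal calibration set,
#' and finally refit on the full table. Folds are grouped by
#' (drug, cell line) pair. Deterministic under a fixed seed
#' (single-threaded training).
#'
#' @param table a `training_table` from [build_training_table()].
#' @param cv list with `repeats` and `folds` for the calibration CV.
#' @param n_search number of randomized hyperparameter draws.
#' @param search_folds folds of the screening CV used to score draws.
#' @param grid named list of candidate hyperparameter values; defaults to
#'   the built-in grid over trees, depth, learning rate, minimum leaf
#'   weight, feature fraction and row subsample.
#' @param seed integer seed for fold assignment, search draws and training.
#' @return an `inhibition_model`: the fitted booster, feature schema
#'   (landmark gene order, fingerprint bit names), pooled calibration
#'   residuals with their out-of-fold predictions, chosen hyperparameters
#'   and CV metadata.
#' @export
fit_inhibition_model <- function(table,
                                 cv = list(repeats = 3L, folds = 10L),
                                 n_search = 8L,
                                 search_folds = 3L,
                                 grid = default_search_grid(),
                                 seed = 1L) {
  stopifnot(inherits(table, "training_table"))
  if (nrow(table) < 100L) {
    stop("InsufficientData: need >= 100 training rows, got ", nrow(table))
  }
  landmark <- attr(table, "landmark_genes")
  fp_bits <- attr(table, "fp_bits")
  groups <- paste(table$drug_id, table$cell_line_id, sep = "\r")
  if (length(unique(groups)) < cv$folds) {
    stop("fit_inhibition_model: fewer distinct (drug, cell line) groups (",
         length(unique(groups)), ") than CV folds (", cv$folds, ")")
  }
  x <- feature_matrix(as.matrix(table[, landmark, drop = FALSE]),
                      as.matrix(table[, fp_bits, drop = FALSE]),
                      table$log10_dose)
  y <- table$inhibition_pct

  set.seed(seed)
  draws <- lapply(seq_len(n_search), function(i) {
    lapply(grid, function(v) v[[sample.int(length(v), 1L)]])
  })
  draws <- unique(draws)

  sfold <- grouped_folds(groups, search_folds)
  score <- vapply(draws, function(hp) {
    se <- 0
    for (f in seq_len(search_folds)) {
      test <- sfold == f
      fit <- xgb_fit(x[!test, , drop = FALSE], y[!test], hp, seed)
      pred <- predict(fit, x[test, , drop = FALSE])
      se <- se + sum((pred - y[test])^2)
    }
    sqrt(se / length(y))
  }, numeric(1))
  best <- draws[[which.min(score)]]

  # repeated grouped CV with the chosen hyperparameters -> calibration set
  oof <- vector("list", cv$repeats)
  for (r in seq_len(cv$repeats)) {
    fold <- grouped_folds(groups, cv$folds)
    pred <- numeric(length(y))
    for (f in seq_len(cv$folds)) {
      test <- fold == f
      fit <- xgb_fit(x[!test, , drop = FALSE], y[!test], best, seed)
      pred[test] <- predict(fit, x[test, , drop = FALSE])
    }
    oof[[r]] <- data.frame(repeat_ = r, row = seq_along(y),
                           observed = y, predicted = pred)
  }
  oof <- do.call(rbind, oof)
  residuals <- abs(oof$observed - oof$predicted)
  cv_rmse <- sqrt(mean((oof$observed - oof$predicted)^2))

  booster <- xgb_fit(x, y, best, seed)
  structure(
    list(
      booster = booster,
      landmark_genes = landmark,
      fp_bits = fp_bits,
      hyperparameters = best,
      search_scores = data.frame(
        draw = seq_along(score),
        rmse = score,
        t(vapply(draws, function(h) unlist(h), unlist(draws[[1]])))
      ),
      calibration_residuals = residuals,
      oof = oof,
      cv = cv,
      cv_rmse = cv_rmse,
      seed = seed,
      n_train = nrow(table)
    ),
    class = "inhibition_model"
  )
}

#' @export
print.inhibition_model <- function(x, ...) {
  cat("<inhibition_model>\n")
  cat(sprintf("  trained on %d rows (%d landmark genes, %d fingerprint bits)\n",
              x$n_train, length(x$landmark_genes), length(x$fp_bits)))
  cat(sprintf("  repeated CV (%d x %d-fold) RMSE: %.2f; %d calibration residuals\n",
              x$cv$repeats, x$cv$folds, x$cv_rmse,
              length(x$calibration_residuals)))
  cat("  hyperparameters: ",
      paste(sprintf("%s=%s", names(x$hyperparameters), x$hyperparameters),
            collapse = ", "), "\n")
  invisible(x)
}

#' Split-conformal interval half-width
#'
#' The order statistic `ceiling((n + 1) * q)` of the calibration
#' residuals: with exchangeable data, an interval of this half-width
#' around a fresh prediction covers the truth with probability at least
#' `q`.
#'
#' @param residuals nonempty vector of held-out absolute residuals.
#' @param q target coverage level in (0, 1).
#' @return the half-width, in percent inhibition.
#' @export
conformal_halfwidth <- function(residuals, q = 0.9) {
  stopifnot(length(residuals) > 0, q > 0, q < 1)
  r <- sort(residuals)
  r[min(length(r), ceiling((length(r) + 1) * q))]
}

# Map a named signature vector onto the model's landmark order; missing
# landmark genes are imputed 0, non-landmark genes dropped.
align_signature <- function(signature, landmark_genes) {
  if (is.null(names(signature))) {
    if (length(signature) != length(landmark_genes)) {
      stop("SchemaMismatch: unnamed signature of length ", length(signature),
           " does not match the ", length(landmark_genes), "-gene landmark panel")
    }
    return(as.numeric(signature))
  }
  out <- stats::setNames(numeric(length(landmark_genes)), landmark_genes)
  hit <- intersect(names(signature), landmark_genes)
  out[hit] <- signature[hit]
  as.numeric(out)
}

#' Predict inhibition for a signature across drugs and doses
#'
#' One prediction record per (drug, dose). Raw model outputs are clipped
#' to \[0, 100\]. The interval half-width is the `q`-th split-conformal
#' quantile of the calibration residuals (global, in percent inhibition),
#' and `confidence = 1 - halfwidth / 100`.
#'
#' @param model an [fit_inhibition_model()] fit.
#' @param signature named numeric vector of log fold changes over (a subset
#'   of) the landmark panel; missing landmark genes are imputed 0.
#' @param fingerprints matrix or data.frame of fingerprint bits, one row
#'   per drug; a `drug_id` column (or rownames) supplies drug ids.
#' @param dose_grid doses (uM) at which to predict each drug.
#' @param q conformal quantile for the interval half-width.
#' @return data.frame: drug_id, dose_uM, predicted_inhibition_pct,
#'   halfwidth, confidence.
#' @export
predict_inhibition <- function(model, signature, fingerprints, dose_grid,
                               q = 0.9) {
  stopifnot(inherits(model, "inhibition_model"), length(dose_grid) >= 1L,
            all(dose_grid > 0))
  if (is.data.frame(fingerprints)) {
    ids <- if ("drug_id" %in% names(fingerprints)) {
      as.character(fingerprints$drug_id)
    } else rownames(fingerprints)
    fp <- as.matrix(fingerprints[, setdiff(names(fingerprints), "drug_id"),
                                 drop = FALSE])
  } else {
    ids <- rownames(fingerprints)
    fp <- as.matrix(fingerprints)
  }
  if (is.null(ids)) ids <- sprintf("drug_%d", seq_len(nrow(fp)))
  if (ncol(fp) != length(model$fp_bits)) {
    stop("SchemaMismatch: fingerprint length ", ncol(fp),
         " differs from training schema (", length(model$fp_bits), " bits)")
  }
  sig <- align_signature(signature, model$landmark_genes)

  nd <- nrow(fp)
  ng <- length(dose_grid)
  sig_mat <- matrix(sig, nd * ng, length(sig), byrow = TRUE,
                    dimnames = list(NULL, model$landmark_genes))
  fp_mat <- fp[rep(seq_len(nd), each = ng), , drop = FALSE]
  colnames(fp_mat) <- model$fp_bits
  doses <- rep(dose_grid, times = nd)
  x <- feature_matrix(sig_mat, fp_mat, log10(doses))
  raw <- predict(model$booster, x)
  hw <- conformal_halfwidth(model$calibration_residuals, q)
  data.frame(
    drug_id = rep(ids, each = ng),
    dose_uM = doses,
    predicted_inhibition_pct = pmin(pmax(raw, 0), 100),
    halfwidth = hw,
    confidence = 1 - hw / 100,
    row.names = NULL
  )
}

#' Drop low-confidence prediction records
#'
#' Keeps records with `confidence >= threshold` (boundary inclusive),
#' preserving order. The default 0.8 mirrors the published cutoff for
#' excluding unreliable treatment-dose predictions.
#'
#' @param records data.frame from [predict_inhibition()].
#' @param threshold minimum confidence kept.
#' @return the filtered records (possibly zero rows).
#' @export
conformal_filter <- function(records, threshold = 0.8) {
  stopifnot("confidence" %in% names(records))
  records[records$confidence >= threshold, , drop = FALSE]
}

#' Drop prediction records above the dose cap
#'
#' Removes records with `dose_uM > cap_uM` (boundary inclusive: a record
#' at exactly the cap survives). The default 1 uM cap favours tolerable,
#' selective predictions.
#'
#' @param records data.frame with a `dose_uM` column.
#' @param cap_uM maximum retained dose, micromolar (may be `Inf`).
#' @return the filtered records.
#' @export
apply_dose_cap <- function(records, cap_uM = 1.0) {
  stopifnot("dose_uM" %in% names(records))
  out <- records[records$dose_uM <= cap_uM, , drop = FALSE]
  if (nrow(out) == 0L && nrow(records) > 0L) {
    warning("apply_dose_cap: all ", nrow(records),
            " records exceed the ", cap_uM, " uM cap")
  }
  out
}

#' Persist / restore an inhibition model
#'
#' The model is written as a versioned directory: the booster in xgboost's
#' native format, the feature schema and metadata as JSON, and the
#' calibration residuals as CSV.
#'
#' @param model an `inhibition_model`.
#' @param dir target directory (created if missing).
#' @return `save_inhibition_model` returns `dir` invisibly;
#'   `load_inhibition_model` returns the restored `inhibition_model`.
#' @export
save_inhibition_model <- function(model, dir) {
  stopifnot(inherits(model, "inhibition_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  meta <- model[setdiff(names(model), c("booster", "calibration_residuals", "oof"))]
  meta$search_scores <- NULL
  jsonlite::write_json(meta, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(residual = model$calibration_residuals),
                   file.path(dir, "residuals.csv"), row.names = FALSE)
  utils::write.csv(model$oof, file.path(dir, "oof.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_inhibition_model
#' @export
load_inhibition_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "schema.json"), simplifyVector = TRUE)
  model <- list(
    booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
    landmark_genes = meta$landmark_genes,
    fp_bits = meta$fp_bits,
    hyperparameters = as.list(meta$hyperparameters),
    calibration_residuals = utils::read.csv(file.path(dir, "residuals.csv"))$residual,
    oof = utils::read.csv(file.path(dir, "oof.csv")),
    cv = as.list(meta$cv),
    cv_rmse = meta$cv_rmse,
    seed = meta$seed,
    n_train = meta$n_train
  )
  class(model) <- "inhibition_model"
  model
}
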