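#' Percent inhibition from plate controls
#'
#' Normalizes a raw viability readout (e.g. luminescence) to the negative
#' control (DMSO, 0% inhibition) and the positive total-kill control
#' (e.g. benzethonium chloride, 100% inhibition):
#' `100 * (dmso_mean - raw) / (dmso_mean - bzcl_mean)`. Values are not
#' clipped: over-killing beyond the positive control reports > 100 so
#' assay artifacts remain visible. Invariant to rescaling all readouts by
#' a common positive factor.
#'
#' @param raw raw readout value(s).
#' @param dmso_mean mean of the negative-control wells.
#' @param bzcl_mean mean of the positive (total-kill) control wells; must
#'   be below `dmso_mean`.
#' @return percent inhibition (unclipped).
#' @export
percent_inhibition <- function(raw, dmso_mean, bzcl_mean) {
  if (!(dmso_mean > bzcl_mean)) {
    stop("DegenerateControls: DMSO control mean (", dmso_mean,
         ") must exceed the total-kill control mean (", bzcl_mean, ")")
  }
  100 * (dmso_mean - raw) / (dmso_mean - bzcl_mean)
}

hill4 <- function(dose, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (ec50 / dose)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit (bottom and top asymptote, EC50, Hill slope)
#' with multi-start Levenberg-Marquardt from a deterministic grid of
#' heuristic initial values; asymptotes are soft-bounded to \[-10, 110\]
#' percent. A dose of 0 evaluates to the bottom asymptote. If every start
#' fails, the fit falls back to a monotone linear interpolant in
#' log10-dose (flagged `fallback = TRUE`).
#'
#' @param doses dose vector, micromolar (>= 3 points; 0 allowed).
#' @param inhibitions percent inhibition at each dose.
#' @return a `hill_fit`: `bottom`, `top`, `ec50_uM`, `slope`, `rmse`,
#'   `fallback`, and the data. Use `predict()` to evaluate it.
#' @export
fit_hill <- function(doses, inhibitions) {
  stopifnot(length(doses) == length(inhibitions))
  if (length(doses) < 3L) {
    stop("fit_hill: need >= 3 dose points, got ", length(doses))
  }
  if (any(doses < 0)) stop("fit_hill: doses must be nonnegative")
  o <- order(doses)
  d <- doses[o]; y <- inhibitions[o]
  pos <- d[d > 0]
  mk <- function(bottom, top, ec50, slope, rmse, fallback = FALSE) {
    structure(list(bottom = bottom, top = top, ec50_uM = ec50, slope = slope,
                   rmse = rmse, fallback = fallback,
                   data = data.frame(dose_uM = d, inhibition_pct = y)),
              class = "hill_fit")
  }
  if (diff(range(y)) < 1e-9 || length(pos) == 0L) {
    # flat response (or no positive dose): slope ~ 0, asymptotes at the mean
    return(mk(mean(y), mean(y), if (length(pos)) exp(mean(log(pos))) else 1,
              0, stats::sd(y) * 0))
  }
  starts <- expand.grid(
    ec50 = unique(c(pos, exp(mean(log(pos))))),
    slope = c(0.5, 1, 2, 4)
  )
  lower <- c(bottom = -10, top = -10,
             ec50 = min(pos) / 100, slope = 0.05)
  upper <- c(bottom = 110, top = 110,
             ec50 = max(pos) * 100, slope = 10)
  best <- NULL; best_sse <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ hill4(d, bottom, top, ec50, slope),
        start = list(bottom = min(y), top = max(y),
                     ec50 = starts$ec50[s], slope = starts$slope[s]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  if (is.null(best)) {
    warning("FitFailure: 4PL fit failed; using monotone linear fallback")
    f <- mk(y[1], y[length(y)], exp(mean(log(pos))), NA_real_,
            NA_real_, fallback = TRUE)
    return(f)
  }
  p <- as.list(stats::coef(best))
  mk(p$bottom, p$top, p$ec50, p$slope, sqrt(best_sse / length(y)))
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose_uM else as.numeric(newdata)
  if (object$fallback) {
    dd <- object$data
    pos <- dd$dose_uM > 0
    out <- numeric(length(d))
    zero_val <- if (any(!pos)) mean(dd$inhibition_pct[!pos]) else
      dd$inhibition_pct[which.min(dd$dose_uM)]
    out[d == 0] <- zero_val
    if (any(d > 0)) {
      out[d > 0] <- stats::approx(log10(dd$dose_uM[pos]),
                                  dd$inhibition_pct[pos],
                                  xout = log10(d[d > 0]), rule = 2,
                                  ties = mean)$y
    }
    return(out)
  }
  if (object$slope == 0) return(rep(object$bottom, length(d)))
  hill4(d, object$bottom, object$top, object$ec50_uM, object$slope)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> bottom=%.2f top=%.2f EC50=%.4g uM slope=%.2f rmse=%.3f%s\n",
              x$bottom, x$top, x$ec50_uM, x$slope, x$rmse,
              if (x$fallback) " [fallback]" else ""))
  invisible(x)
}

#' Dose-response combination matrix
#'
#' Container for a two-drug percent-inhibition grid including the
#' zero-dose row and column (the monotherapy margins). Row doses belong
#' to drug 1, column doses to drug 2; both must start at 0 and increase
#' strictly.
#'
#' @param row_doses,col_doses dose vectors (uM), starting at 0.
#' @param inhibition matrix of percent inhibitions,
#'   `length(row_doses)` x `length(col_doses)`.
#' @return a `dose_response_matrix`.
#' @export
dose_response_matrix <- function(row_doses, col_doses, inhibition) {
  inhibition <- as.matrix(inhibition)
  stopifnot(nrow(inhibition) == length(row_doses),
            ncol(inhibition) == length(col_doses))
  if (row_doses[1] != 0 || col_doses[1] != 0) {
    stop("dose_response_matrix: monotherapy margins required ",
         "(both dose vectors must start at 0)")
  }
  if (any(diff(row_doses) <= 0) || any(diff(col_doses) <= 0)) {
    stop("dose_response_matrix: doses must be strictly increasing")
  }
  structure(list(row_doses = row_doses, col_doses = col_doses,
                 inhibition = inhibition),
            class = "dose_response_matrix")
}

#' ZIP synergy delta of a dose-response matrix
#'
#' Bliss-referenced zero-interaction-potency delta: 4PL curves are fitted
#' to the two monotherapy margins; the zero-interaction expectation at
#' each interior dose pair is `f1 + f2 - f1*f2` on the fractional-effect
#' scale (fitted margins clipped to \[0, 1\]); the score is the mean of
#' (observed - expected) over the interior cells, times 100. Exactly 0
#' when the interior is Bliss-consistent with its own margins; in the
#' published convention, delta > 10 reads as synergy and 0-10 as
#' additivity. An optional `region` restricts the average to a dose
#' window around the predicted effective doses. Margins with fewer than
#' three points are used raw (a 4PL is not identifiable there).
#'
#' @param mat a [dose_response_matrix()].
#' @param region optional list with `drug_a` and/or `drug_b`, each a
#'   `c(lo, hi)` dose window (uM) restricting the interior cells used.
#' @return the ZIP delta on the percent scale; fitted margins are
#'   attached as attributes.
#' @export
zip_score <- function(mat, region = NULL) {
  stopifnot(inherits(mat, "dose_response_matrix"))
  # margins with fewer than 3 points carry nothing to fit: use them raw
  margin <- function(doses, inhib) {
    if (length(doses) < 3L) return(inhib)
    predict(fit_hill(doses, inhib), doses)
  }
  f1 <- pmin(pmax(margin(mat$row_doses, mat$inhibition[, 1]) / 100, 0), 1)
  f2 <- pmin(pmax(margin(mat$col_doses, mat$inhibition[1, ]) / 100, 0), 1)
  expected <- outer(f1, f2, function(a, b) a + b - a * b)
  delta <- mat$inhibition / 100 - expected
  use_r <- seq_along(mat$row_doses)[-1]
  use_c <- seq_along(mat$col_doses)[-1]
  if (!is.null(region$drug_a)) {
    use_r <- use_r[mat$row_doses[use_r] >= region$drug_a[1] &
                   mat$row_doses[use_r] <= region$drug_a[2]]
  }
  if (!is.null(region$drug_b)) {
    use_c <- use_c[mat$col_doses[use_c] >= region$drug_b[1] &
                   mat$col_doses[use_c] <= region$drug_b[2]]
  }
  if (length(use_r) == 0L || length(use_c) == 0L) {
    stop("zip_score: the dose region excludes every interior cell")
  }
  out <- 100 * mean(delta[use_r, use_c])
  attr(out, "margin_a_pct") <- 100 * f1
  attr(out, "margin_b_pct") <- 100 * f2
  out
}

#' Drug sensitivity score (normalized dose-response AUC)
#'
#' Integrates the fitted inhibition curve above an activity threshold
#' over a log10-dose window and normalizes by the maximal attainable
#' area: `100 * integral(max(0, f(d) - t)) / ((100 - t) * window)`.
#' A curve pinned at the threshold scores 0; a curve pinned at 100%
#' scores 100.
#'
#' @param fit a [fit_hill()] result.
#' @param dose_range `c(lo, hi)` integration window, micromolar (lo > 0).
#' @param activity_threshold percent inhibition subtracted before
#'   integration.
#' @return DSS in \[0, 100\].
#' @export
dss <- function(fit, dose_range, activity_threshold = 10) {
  stopifnot(inherits(fit, "hill_fit"))
  if (length(dose_range) != 2L || any(dose_range <= 0) ||
      dose_range[2] <= dose_range[1]) {
    stop("InvalidRange: dose_range must be an increasing positive interval")
  }
  lo <- log10(dose_range[1]); hi <- log10(dose_range[2])
  integrand <- function(t) {
    pmax(0, predict(fit, 10^t) - activity_threshold)
  }
  area <- stats::integrate(integrand, lo, hi, subdivisions = 500L,
                           rel.tol = 1e-8, abs.tol = 1e-10)$value
  100 * area / ((100 - activity_threshold) * (hi - lo))
}

#' ROC area under the curve
#'
#' Rank-statistic AUC with tie correction (higher scores indicate the
#' positive class), computed with pROC.
#'
#' @param labels logical (or 0/1) class labels; both classes required.
#' @param scores numeric classifier scores, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  if (length(unique(labels)) < 2L) {
    stop("OneClassOnly: both classes must be present")
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' DeLong test for two paired ROC curves
#'
#' Two-sided DeLong comparison of two classifiers scored on the same
#' cases (covariance via placement values, as implemented in pROC).
#' Identical score vectors return `z = 0`, `p = 1`.
#'
#' @param labels logical (or 0/1) class labels; both classes required.
#' @param scores1,scores2 paired score vectors.
#' @return list with `z` (statistic), `p` (two-sided p-value), and the
#'   two AUCs.
#' @export
delong_test <- function(labels, scores1, scores2) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores1),
            length(labels) == length(scores2))
  if (length(unique(labels)) < 2L) {
    stop("OneClassOnly: both classes must be present")
  }
  auc1 <- roc_auc(labels, scores1)
  auc2 <- roc_auc(labels, scores2)
  if (isTRUE(all.equal(scores1, scores2))) {
    return(list(z = 0, p = 1, auc1 = auc1, auc2 = auc2))
  }
  r1 <- pROC::roc(response = labels, predictor = scores1,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(response = labels, predictor = scores2,
                  levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  tt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  z <- as.numeric(tt$statistic)
  p <- as.numeric(tt$p.value)
  if (!is.finite(z)) { z <- 0; p <- 1 }
  list(z = z, p = p, auc1 = auc1, auc2 = auc2)
}
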