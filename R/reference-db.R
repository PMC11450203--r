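#' Interpolate percent inhibition from a viability curve
#'
#' Linear interpolation of viability in log10-dose space at `query_dose`,
#' returned as inhibition `100 - viability`, clipped to \[0, 100\].
#' Measured doses reproduce their measured values exactly (knot
#' exactness); queries outside the measured span raise an error rather
#' than extrapolating the sigmoid tails.
#'
#' @param dose_uM measured doses, micromolar (need not be sorted).
#' @param viability_pct measured viabilities, percent.
#' @param query_dose dose(s) at which to evaluate, micromolar.
#' @return percent inhibition in \[0, 100\], one value per query dose.
#' @export
#' @examples
#' interpolate_inhibition(c(0.1, 1), c(80, 40), 0.316227766) # log-midpoint: 40
interpolate_inhibition <- function(dose_uM, viability_pct, query_dose) {
  stopifnot(length(dose_uM) == length(viability_pct))
  if (length(unique(dose_uM)) < 2L) {
    stop("interpolate_inhibition: need >= 2 distinct doses")
  }
  if (any(dose_uM <= 0) || any(query_dose <= 0)) {
    stop("interpolate_inhibition: doses must be positive")
  }
  o <- order(dose_uM)
  lx <- log10(dose_uM[o])
  y <- viability_pct[o]
  lq <- log10(query_dose)
  if (any(lq < min(lx) - 1e-12) || any(lq > max(lx) + 1e-12)) {
    stop("OutOfRange: query dose outside the measured dose span [",
         signif(min(dose_uM), 3), ", ", signif(max(dose_uM), 3), "] uM")
  }
  v <- stats::approx(lx, y, xout = lq, ties = mean)$y
  pmin(pmax(100 - v, 0), 100)
}

#' Assemble the model training table
#'
#' Inner-joins perturbation signatures with dose-response curves on
#' (drug, cell line), interpolating each curve at the perturbation dose to
#' obtain the inhibition target, and attaches the drug fingerprint.
#' Perturbation rows without a matching curve, with fewer than `min_doses`
#' distinct curve doses, or with a dose outside the measured curve span
#' are dropped (counts reported in `attr(, "skipped")`); nothing is
#' extrapolated. Duplicate (drug, cell line, dose) perturbations are all
#' retained. Rows are ordered by (drug_id, cell_line_id, dose_uM)
#' regardless of input order.
#'
#' @param perturbations data.frame: drug_id, cell_line_id, dose_uM, then
#'   one column per landmark gene (log fold changes).
#' @param curves data.frame: drug_id, cell_line_id, dose_uM, viability_pct.
#' @param fingerprints data.frame: drug_id, then bit columns in \{0, 1\}.
#' @return a `training_table`: data.frame with id columns (drug_id,
#'   cell_line_id, dose_uM), the landmark signature columns, the
#'   fingerprint bit columns, `log10_dose`, and the target
#'   `inhibition_pct` in \[0, 100\]. Attributes `landmark_genes`,
#'   `fp_bits` and `skipped` describe the schema and the join log.
#' @export
build_training_table <- function(perturbations, curves, fingerprints) {
  id_cols <- c("drug_id", "cell_line_id", "dose_uM")
  stopifnot(all(id_cols %in% names(perturbations)),
            all(c(id_cols, "viability_pct") %in% names(curves)),
            "drug_id" %in% names(fingerprints))
  landmark <- setdiff(names(perturbations), id_cols)
  fp_bits <- setdiff(names(fingerprints), "drug_id")
  if (anyDuplicated(fingerprints$drug_id)) {
    stop("build_training_table: duplicated drug_id in fingerprint table")
  }

  pert <- perturbations[order(perturbations$drug_id,
                              perturbations$cell_line_id,
                              perturbations$dose_uM), , drop = FALSE]
  pair <- paste(pert$drug_id, pert$cell_line_id, sep = "\r")
  curve_pair <- paste(curves$drug_id, curves$cell_line_id, sep = "\r")
  curve_split <- split(seq_len(nrow(curves)), curve_pair)

  n <- nrow(pert)
  target <- rep(NA_real_, n)
  skipped <- c(no_curve = 0L, too_few_doses = 0L, out_of_range = 0L)
  for (p in unique(pair)) {
    rows <- which(pair == p)
    ci <- curve_split[[p]]
    if (is.null(ci)) {
      skipped["no_curve"] <- skipped["no_curve"] + length(rows)
      next
    }
    if (length(unique(curves$dose_uM[ci])) < 2L) {
      skipped["too_few_doses"] <- skipped["too_few_doses"] + length(rows)
      next
    }
    lo <- min(curves$dose_uM[ci]); hi <- max(curves$dose_uM[ci])
    for (r in rows) {
      d <- pert$dose_uM[r]
      if (d < lo * (1 - 1e-12) || d > hi * (1 + 1e-12)) {
        skipped["out_of_range"] <- skipped["out_of_range"] + 1L
        next
      }
      target[r] <- interpolate_inhibition(curves$dose_uM[ci],
                                          curves$viability_pct[ci], d)
    }
  }
  keep <- !is.na(target)
  if (!any(keep)) stop("EmptyJoin: no perturbation row survived the join")
  no_fp <- !(pert$drug_id %in% fingerprints$drug_id)
  if (any(keep & no_fp)) {
    skipped <- c(skipped, no_fingerprint = sum(keep & no_fp))
    keep <- keep & !no_fp
    if (!any(keep)) stop("EmptyJoin: no perturbation row survived the join")
  }

  pert <- pert[keep, , drop = FALSE]
  fpm <- fingerprints[match(pert$drug_id, fingerprints$drug_id),
                      fp_bits, drop = FALSE]
  out <- data.frame(
    pert[id_cols],
    pert[landmark],
    fpm,
    log10_dose = log10(pert$dose_uM),
    inhibition_pct = target[keep],
    check.names = FALSE,
    row.names = NULL
  )
  attr(out, "landmark_genes") <- landmark
  attr(out, "fp_bits") <- fp_bits
  attr(out, "skipped") <- skipped
  class(out) <- c("training_table", "data.frame")
  out
}

#' Circular fingerprint from a SMILES string (real-data mode)
#'
#' Radius-2 extended-connectivity fingerprint (ECFP4) computed with Open
#' Babel through ChemmineOB and folded to `n_bits` by OR-ing bit positions
#' modulo `n_bits`. Requires the suggested ChemmineOB package.
#'
#' @param smiles a single SMILES string.
#' @param n_bits fingerprint length; must divide 4096.
#' @return integer vector of `n_bits` bits.
#' @export
fingerprint_from_smiles <- function(smiles, n_bits = 1024L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint_from_smiles requires the ChemmineOB package ",
         "(real-SMILES mode); synthetic fingerprints do not")
  }
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (4096L %% as.integer(n_bits) != 0L) {
    stop("fingerprint_from_smiles: n_bits must divide 4096")
  }
  if (!nzchar(trimws(smiles))) stop("ParseError: empty SMILES string")
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "ECFP4"),
    error = function(e) NULL)
  if (is.null(raw) || length(raw) != 4096L || all(is.na(raw))) {
    stop("ParseError: invalid SMILES string: ", smiles)
  }
  folded <- as.integer(rowSums(matrix(as.integer(raw > 0), nrow = n_bits)) > 0)
  stats::setNames(folded, sprintf("bit_%d", seq_len(n_bits) - 1L))
}
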