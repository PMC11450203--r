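#' Rank the drug library for one clone
#'
#' Predicts inhibition for the clone signature over every (drug, dose) in
#' the library and dose grid, applies the conformal confidence filter and
#' the dose cap, and keeps each drug's best surviving dose (highest
#' predicted inhibition; ties broken by the lower dose, then drug id).
#' The result is sorted by predicted inhibition, descending.
#'
#' @param model an [fit_inhibition_model()] fit.
#' @param signature named landmark log2 fold-change vector (e.g. from
#'   [landmark_signature()]); a signature with no nonzero entry is refused.
#' @param drug_library fingerprint data.frame (`drug_id` + bit columns).
#' @param dose_grid doses (uM) evaluated per drug.
#' @param threshold confidence cutoff (see [conformal_filter()]).
#' @param cap_uM dose cap (see [apply_dose_cap()]).
#' @param clone_id label stored on the result.
#' @return a `clone_prediction_set`: data.frame with `clone`, `drug_id`,
#'   `dose_uM`, `predicted_inhibition_pct`, `halfwidth`, `confidence`,
#'   `rank`; `attr(, "mode")` is "combination" by default.
#' @export
rank_for_clone <- function(model, signature, drug_library,
                           dose_grid = c(0.01, 0.0316, 0.1, 0.316, 1),
                           threshold = 0.8, cap_uM = 1.0,
                           clone_id = "A") {
  if (all(abs(signature) < 1e-12)) {
    stop("EmptyAfterFilters: signature has no differentially expressed ",
         "landmark gene; no prediction attempted for clone ", clone_id)
  }
  rec <- predict_inhibition(model, signature, drug_library, dose_grid)
  rec <- conformal_filter(rec, threshold)
  rec <- apply_dose_cap(rec, cap_uM)
  if (nrow(rec) == 0L) {
    stop("EmptyAfterFilters: no (drug, dose) prediction survived the ",
         "confidence filter and dose cap for clone ", clone_id)
  }
  # best dose per drug: highest prediction, ties -> lower dose
  rec <- rec[order(rec$drug_id, -rec$predicted_inhibition_pct, rec$dose_uM), ]
  rec <- rec[!duplicated(rec$drug_id), , drop = FALSE]
  rec <- rec[order(-rec$predicted_inhibition_pct, rec$dose_uM, rec$drug_id), ]
  out <- data.frame(clone = clone_id, rec, rank = seq_len(nrow(rec)),
                    row.names = NULL)
  attr(out, "mode") <- "combination"
  class(out) <- c("clone_prediction_set", "data.frame")
  out
}

#' Monotherapy ranking on the pooled malignant signature
#'
#' Identical ranking contract to [rank_for_clone()], applied to the pooled
#' all-malignant-versus-normal signature, returning the top `top_k`
#' surviving drugs (fewer if the confidence filter removes some).
#'
#' @inheritParams rank_for_clone
#' @param top_k maximum number of drugs returned.
#' @return a `clone_prediction_set` with mode "monotherapy".
#' @export
monotherapy_mode <- function(model, signature, drug_library,
                             dose_grid = c(0.01, 0.0316, 0.1, 0.316, 1),
                             threshold = 0.8, cap_uM = 1.0, top_k = 20L) {
  out <- rank_for_clone(model, signature, drug_library, dose_grid,
                        threshold, cap_uM, clone_id = "malignant")
  out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  attr(out, "mode") <- "monotherapy"
  class(out) <- c("clone_prediction_set", "data.frame")
  out
}

# dose bracket note: one dilution step below and above the predicted dose
dose_bracket <- function(dose, fold = 10) {
  sprintf("test %.4g / %.4g / %.4g uM", dose / fold, dose, dose * fold)
}

#' Design two-drug combination plans
#'
#' Candidate pairs are drawn from the top `k` records of each clone's
#' prediction set; pairs sharing a drug are excluded (the enumeration over
#' the top-k automatically supplies the next-ranked substitutes). Pairs
#' are ranked by the combined score, the unweighted mean of the two
#' predicted inhibitions. Each drug carries a dose-bracket note
#' recommending one dilution step above and below its predicted dose.
#'
#' @param set_a,set_b `clone_prediction_set`s for subclones A and B.
#' @param k number of top records considered per clone.
#' @param dilution_fold dilution step of the dose bracket.
#' @return data.frame of `combination_plan`s: drug/dose for each clone,
#'   `combined_score`, `rank`, and bracket notes.
#' @export
design_combinations <- function(set_a, set_b, k = 6L, dilution_fold = 10) {
  stopifnot(nrow(set_a) > 0, nrow(set_b) > 0)
  a <- utils::head(set_a, k)
  b <- utils::head(set_b, k)
  pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  pairs <- pairs[a$drug_id[pairs$i] != b$drug_id[pairs$j], , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("NoValidPairs: every candidate pair shares a drug")
  }
  out <- data.frame(
    drug_a = a$drug_id[pairs$i],
    dose_a_uM = a$dose_uM[pairs$i],
    inhibition_a = a$predicted_inhibition_pct[pairs$i],
    drug_b = b$drug_id[pairs$j],
    dose_b_uM = b$dose_uM[pairs$j],
    inhibition_b = b$predicted_inhibition_pct[pairs$j],
    row.names = NULL
  )
  out$combined_score <- (out$inhibition_a + out$inhibition_b) / 2
  out <- out[order(-out$combined_score, out$drug_a, out$drug_b), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$bracket_a <- dose_bracket(out$dose_a_uM, dilution_fold)
  out$bracket_b <- dose_bracket(out$dose_b_uM, dilution_fold)
  rownames(out) <- NULL
  class(out) <- c("combination_plan", "data.frame")
  out
}

#' End-to-end therapy design from a clone map
#'
#' Convenience wrapper: in combination mode, ranks the library for each
#' subclone signature and assembles combination plans; in monotherapy
#' mode, ranks the pooled malignant signature. An optional selectivity
#' filter drops drugs predicted at or above `normal_inhibition_max` on a
#' user-supplied normal-cell signature (off by default).
#'
#' @param clone_map a [call_clones()] result.
#' @param model an [fit_inhibition_model()] fit.
#' @param drug_library fingerprint data.frame.
#' @param dose_grid,threshold,cap_uM,top_k,k_pairs ranking parameters.
#' @param normal_signature optional named landmark vector for normal cells.
#' @param normal_inhibition_max drop drugs predicted at or above this
#'   inhibition on `normal_signature` (toxicity proxy).
#' @return list with `mode`, `predictions` (per clone) and, in
#'   combination mode, `combinations`.
#' @export
design_therapies <- function(clone_map, model, drug_library,
                             dose_grid = c(0.01, 0.0316, 0.1, 0.316, 1),
                             threshold = 0.8, cap_uM = 1.0,
                             top_k = 20L, k_pairs = 6L,
                             normal_signature = NULL,
                             normal_inhibition_max = 50) {
  stopifnot(inherits(clone_map, "clone_map"))
  lm_genes <- model$landmark_genes
  drop_toxic <- function(set) {
    if (is.null(normal_signature)) return(set)
    nrec <- predict_inhibition(model, normal_signature, drug_library,
                               set$dose_uM[1])
    toxic <- unique(nrec$drug_id[
      nrec$predicted_inhibition_pct >= normal_inhibition_max])
    out <- set[!set$drug_id %in% toxic, , drop = FALSE]
    attr(out, "mode") <- attr(set, "mode")
    class(out) <- class(set)
    out
  }
  if (clone_map$mode == "combination") {
    sets <- lapply(c(A = "A", B = "B"), function(cl) {
      drop_toxic(rank_for_clone(
        model, landmark_signature(clone_map$signatures[[cl]], lm_genes),
        drug_library, dose_grid, threshold, cap_uM, clone_id = cl))
    })
    list(mode = "combination", predictions = sets,
         combinations = design_combinations(sets$A, sets$B, k = k_pairs))
  } else {
    set <- drop_toxic(monotherapy_mode(
      model, landmark_signature(clone_map$signatures[["malignant"]], lm_genes),
      drug_library, dose_grid, threshold, cap_uM, top_k = top_k))
    list(mode = "monotherapy", predictions = list(malignant = set))
  }
}
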