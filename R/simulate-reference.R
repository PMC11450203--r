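#' Hill (log-logistic) inhibition curve
#'
#' Percent inhibition at a given dose under a three-parameter Hill model
#' with zero baseline: `emax * dose^slope / (dose^slope + ec50^slope)`.
#' At `dose == ec50` the value is exactly `emax / 2`; at dose 0 it is 0.
#'
#' @param dose dose(s), micromolar; nonnegative.
#' @param ec50 half-maximal dose, micromolar.
#' @param slope Hill slope (unitless, > 0).
#' @param emax maximal inhibition, percent in \[0, 100\].
#' @return percent inhibition, same length as `dose`.
#' @export
#' @examples
#' hill_inhibition(c(0, 1, 1e6), ec50 = 1, slope = 1, emax = 80)
hill_inhibition <- function(dose, ec50, slope, emax) {
  stopifnot(all(dose >= 0), ec50 > 0, slope > 0, emax >= 0, emax <= 100)
  r <- (dose / ec50)^slope
  emax * r / (1 + r)
}

# Landmark gene symbols: zero-padded LM ids shared between the reference
# tables and the synthetic patient so signatures line up by name.
landmark_gene_names <- function(n) sprintf("LM%04d", seq_len(n))

drug_ids <- function(n) sprintf("D%03d", seq_len(n))
cell_line_ids <- function(n) sprintf("C%03d", seq_len(n))

# Drug-, class- and cell-line-level ground truth shared by both simulators.
# Drawn under set.seed(cfg$seed) so simulate_reference() and
# simulate_patient() agree on modules, Hill parameters and sensitivities
# without passing objects between them.
reference_truth <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  L <- cfg$n_landmark_genes
  K <- cfg$n_target_classes
  genes <- landmark_gene_names(L)

  # disjoint class modules over the landmark panel, signed effects
  pool <- sample.int(L, K * cfg$module_size)
  modules <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- pool[((k - 1) * cfg$module_size + 1):(k * cfg$module_size)]
    eff <- stats::runif(cfg$module_size, 0.5, 2) *
      sample(c(-1, 1), cfg$module_size, replace = TRUE)
    modules[[k]] <- data.frame(gene = genes[idx], index = idx, effect = eff)
  }
  # class-level transcriptional responsiveness: scales signature amplitude
  # per unit inhibition, so inhibition cannot be read off the signature
  # without knowing the drug's class (forces fingerprint use by the model)
  responsiveness <- stats::runif(K, 0.6, 1.4)

  # structural fingerprint templates per class; drugs are analogs of their
  # class template with a 10% per-bit flip rate
  templates <- matrix(stats::rbinom(K * cfg$n_fp_bits, 1L, 0.5),
                      nrow = K, ncol = cfg$n_fp_bits)

  dclass <- rep_len(seq_len(K), cfg$n_drugs)
  fp <- matrix(0L, cfg$n_drugs, cfg$n_fp_bits,
               dimnames = list(drug_ids(cfg$n_drugs),
                               sprintf("bit_%d", seq_len(cfg$n_fp_bits) - 1L)))
  for (d in seq_len(cfg$n_drugs)) {
    flip <- stats::rbinom(cfg$n_fp_bits, 1L, 0.1)
    fp[d, ] <- as.integer(xor(templates[dclass[d], ], flip))
  }

  drugs <- data.frame(
    drug_id = drug_ids(cfg$n_drugs),
    target_class = dclass,
    ec50_uM = exp(stats::runif(cfg$n_drugs,
                               log(cfg$hill_ec50_range[1]),
                               log(cfg$hill_ec50_range[2]))),
    slope = stats::runif(cfg$n_drugs, cfg$hill_slope_range[1],
                         cfg$hill_slope_range[2]),
    emax = stats::runif(cfg$n_drugs, cfg$hill_emax_range[1],
                        cfg$hill_emax_range[2])
  )

  # cell-line sensitivity multipliers in (0.3, 1): scales the whole curve
  sens <- matrix(stats::runif(cfg$n_cell_lines * cfg$n_drugs, 0.3, 1),
                 nrow = cfg$n_cell_lines, ncol = cfg$n_drugs,
                 dimnames = list(cell_line_ids(cfg$n_cell_lines),
                                 drugs$drug_id))

  structure(
    list(landmark_genes = genes, modules = modules,
         responsiveness = responsiveness, drugs = drugs,
         fingerprints = fp, sensitivity = sens, config = cfg),
    class = "reference_truth"
  )
}

# true percent inhibition for (drug index, cell line index, dose)
true_inhibition <- function(truth, drug_idx, cell_idx, dose) {
  d <- truth$drugs[drug_idx, ]
  r <- (dose / d$ec50_uM)^d$slope
  truth$sensitivity[cbind(cell_idx, drug_idx)] * d$emax * r / (1 + r)
}

#' Simulate the perturbation/viability/fingerprint reference database
#'
#' Generates the three tables the training-table builder consumes, plus the
#' generative ground truth. For each (drug, cell line, perturbation dose)
#' the landmark signature equals the class module effects scaled by class
#' responsiveness times fractional inhibition, plus Gaussian noise.
#' Viability curves are sampled from the per-curve Hill model on a
#' log10-spaced dose grid that brackets the perturbation grid, with
#' Gaussian noise. Fingerprints are deterministic per drug. Identical
#' configurations (including seed) give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `perturbations` (data.frame: drug_id,
#'   cell_line_id, dose_uM, one column per landmark gene),
#'   `curves` (data.frame: drug_id, cell_line_id, dose_uM, viability_pct),
#'   `fingerprints` (data.frame: drug_id, bit_0 ... bit_B-1) and
#'   `truth` (class `reference_truth`, with a `$perturbation_truth`
#'   data.frame of noise-free inhibitions for every perturbation row).
#' @seealso [simulate_patient()], [build_training_table()]
#' @export
simulate_reference <- function(cfg) {
  truth <- reference_truth(cfg)
  set.seed(cfg$seed + 1L)

  nd <- cfg$n_drugs
  nc <- cfg$n_cell_lines
  L <- cfg$n_landmark_genes

  pert_doses <- if (cfg$doses_per_drug == 1L) {
    exp(mean(log(cfg$dose_range_uM)))
  } else {
    10^seq(log10(cfg$dose_range_uM[1]), log10(cfg$dose_range_uM[2]),
           length.out = cfg$doses_per_drug)
  }
  # viability measured on its own, wider grid so every perturbation dose
  # is interpolable (mimics independent dose-response assays)
  curve_doses <- 10^seq(log10(cfg$dose_range_uM[1] / 3),
                        log10(cfg$dose_range_uM[2] * 3),
                        length.out = cfg$doses_per_drug + 2L)

  grid <- expand.grid(dose_i = seq_along(pert_doses), cell = seq_len(nc),
                      drug = seq_len(nd))
  grid <- grid[order(grid$drug, grid$cell, grid$dose_i), , drop = FALSE]
  dose <- pert_doses[grid$dose_i]
  inh <- true_inhibition(truth, grid$drug, grid$cell, dose)

  # signature matrix: rows follow grid order
  sig <- matrix(stats::rnorm(nrow(grid) * L, 0, cfg$signature_noise_sd),
                nrow = nrow(grid), ncol = L)
  colnames(sig) <- truth$landmark_genes
  for (k in seq_len(cfg$n_target_classes)) {
    rows <- truth$drugs$target_class[grid$drug] == k
    if (!any(rows)) next
    m <- truth$modules[[k]]
    amp <- truth$responsiveness[k] * inh[rows] / 100
    sig[rows, m$index] <- sig[rows, m$index] + outer(amp, m$effect)
  }
  perturbations <- data.frame(
    drug_id = truth$drugs$drug_id[grid$drug],
    cell_line_id = rownames(truth$sensitivity)[grid$cell],
    dose_uM = dose,
    sig,
    check.names = FALSE
  )
  truth$perturbation_truth <- data.frame(
    drug_id = perturbations$drug_id,
    cell_line_id = perturbations$cell_line_id,
    dose_uM = dose,
    true_inhibition = inh
  )

  cg <- expand.grid(dose_i = seq_along(curve_doses), cell = seq_len(nc),
                    drug = seq_len(nd))
  cg <- cg[order(cg$drug, cg$cell, cg$dose_i), , drop = FALSE]
  cdose <- curve_doses[cg$dose_i]
  cinh <- true_inhibition(truth, cg$drug, cg$cell, cdose)
  viability <- 100 - cinh +
    stats::rnorm(nrow(cg), 0, cfg$noise_sd_viability)
  curves <- data.frame(
    drug_id = truth$drugs$drug_id[cg$drug],
    cell_line_id = rownames(truth$sensitivity)[cg$cell],
    dose_uM = cdose,
    viability_pct = viability
  )

  fingerprints <- data.frame(drug_id = rownames(truth$fingerprints),
                             truth$fingerprints, check.names = FALSE,
                             row.names = NULL)

  list(perturbations = perturbations, curves = curves,
       fingerprints = fingerprints, truth = truth)
}
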