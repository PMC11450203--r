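#' Simulation configuration
#'
#' Bundles every tunable of the synthetic data generator: the size of the
#' perturbation/viability reference (drugs, cell lines, landmark panel,
#' fingerprint width, dose grid), the Hill-curve parameter ranges used to
#' draw ground-truth dose-response curves, and the composition of the
#' synthetic patient (cells, clone fractions, arm-level CNV events,
#' mitochondrial content).
#'
#' Drugs are grouped into `n_target_classes` target classes. Each class owns
#' a module of `module_size` landmark genes with signed effect sizes and a
#' class-level transcriptional responsiveness; drugs of a class share the
#' module and a structural fingerprint template. Malignant clones in the
#' synthetic patient are planted with the module of one class each, so the
#' drugs of that class are the ground-truth matched treatments for the clone.
#'
#' @param n_drugs number of drugs in the reference library.
#' @param n_cell_lines number of cell lines the reference is measured in.
#' @param n_landmark_genes size of the landmark gene panel over which
#'   perturbation and patient signatures are expressed.
#' @param n_fp_bits fingerprint length in bits.
#' @param doses_per_drug number of perturbation doses per drug (1-35).
#' @param dose_range_uM span of the perturbation dose grid, micromolar.
#' @param hill_ec50_range,hill_slope_range,hill_emax_range ranges from which
#'   per-drug Hill EC50 (uM), slope and maximal inhibition (%) are drawn.
#' @param n_target_classes number of drug target classes (each with its own
#'   landmark gene module).
#' @param module_size genes per target-class module.
#' @param signature_noise_sd Gaussian noise SD added to every landmark
#'   log-fold-change entry of a perturbation signature.
#' @param noise_sd_viability Gaussian noise SD (percent viability) on the
#'   dose-response curves.
#' @param n_cells,n_genes dimensions of the synthetic patient count matrix.
#' @param clone_fractions named simplex vector of cell fractions; must
#'   contain a `normal` entry plus one entry per malignant clone.
#' @param cnv_events named list (one entry per clone) of lists of
#'   `list(arm =, ratio =)` arm-level copy-ratio events.
#' @param clone_module_amplitude log2 fold-change scale of the planted
#'   clone expression modules (before class responsiveness scaling).
#' @param n_mito_genes,mito_baseline_frac number of mitochondrial genes and
#'   their baseline share of per-cell UMI counts.
#' @param high_mito_fraction,high_mito_level fraction of cells simulated as
#'   damaged (elevated mitochondrial share `high_mito_level`), for QC tests.
#' @param seed integer seed; identical configurations yield bit-identical
#'   simulations.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_drugs = 10, n_cell_lines = 4, seed = 1)
sim_config <- function(n_drugs = 50,
                       n_cell_lines = 20,
                       n_landmark_genes = 200,
                       n_fp_bits = 256,
                       doses_per_drug = 8,
                       dose_range_uM = c(0.001, 10),
                       hill_ec50_range = c(0.01, 5),
                       hill_slope_range = c(0.7, 2),
                       hill_emax_range = c(60, 100),
                       n_target_classes = 10,
                       module_size = 15,
                       signature_noise_sd = 0.15,
                       noise_sd_viability = 5,
                       n_cells = 600,
                       n_genes = 2000,
                       clone_fractions = c(normal = 0.4, A = 0.35, B = 0.25),
                       cnv_events = list(
                         A = list(list(arm = "1p", ratio = 1.5),
                                  list(arm = "3p", ratio = 0.5)),
                         B = list(list(arm = "7q", ratio = 0.5),
                                  list(arm = "9q", ratio = 1.5))
                       ),
                       clone_module_amplitude = 1.0,
                       n_mito_genes = 13,
                       mito_baseline_frac = 0.05,
                       high_mito_fraction = 0,
                       high_mito_level = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs),
    n_cell_lines = as.integer(n_cell_lines),
    n_landmark_genes = as.integer(n_landmark_genes),
    n_fp_bits = as.integer(n_fp_bits),
    doses_per_drug = as.integer(doses_per_drug),
    dose_range_uM = as.numeric(dose_range_uM),
    hill_ec50_range = as.numeric(hill_ec50_range),
    hill_slope_range = as.numeric(hill_slope_range),
    hill_emax_range = as.numeric(hill_emax_range),
    n_target_classes = as.integer(n_target_classes),
    module_size = as.integer(module_size),
    signature_noise_sd = as.numeric(signature_noise_sd),
    noise_sd_viability = as.numeric(noise_sd_viability),
    n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes),
    clone_fractions = clone_fractions,
    cnv_events = cnv_events,
    clone_module_amplitude = as.numeric(clone_module_amplitude),
    n_mito_genes = as.integer(n_mito_genes),
    mito_baseline_frac = as.numeric(mito_baseline_frac),
    high_mito_fraction = as.numeric(high_mito_fraction),
    high_mito_level = as.numeric(high_mito_level),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(
    n_drugs = cfg$n_drugs, n_cell_lines = cfg$n_cell_lines,
    n_landmark_genes = cfg$n_landmark_genes, n_fp_bits = cfg$n_fp_bits,
    n_cells = cfg$n_cells, n_genes = cfg$n_genes,
    n_target_classes = cfg$n_target_classes, module_size = cfg$module_size
  )
  if (any(counts <= 0)) {
    stop("sim_config: all counts must be > 0 (offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "), ")")
  }
  if (cfg$doses_per_drug < 1L || cfg$doses_per_drug > 35L) {
    stop("sim_config: doses_per_drug must lie in [1, 35]")
  }
  if (abs(sum(cfg$clone_fractions) - 1) > 1e-8) {
    stop("sim_config: clone_fractions must sum to 1")
  }
  if (any(cfg$clone_fractions < 0)) {
    stop("sim_config: clone_fractions must be nonnegative")
  }
  if (is.null(names(cfg$clone_fractions)) || any(names(cfg$clone_fractions) == "")) {
    stop("sim_config: clone_fractions must be a named vector")
  }
  if (cfg$n_target_classes * cfg$module_size > cfg$n_landmark_genes) {
    stop("sim_config: n_target_classes * module_size exceeds the landmark panel; ",
         "modules are drawn disjoint")
  }
  if (length(cfg$dose_range_uM) != 2L || any(cfg$dose_range_uM <= 0) ||
      diff(cfg$dose_range_uM) < 0) {
    stop("sim_config: dose_range_uM must be an increasing positive interval")
  }
  if (cfg$n_genes < cfg$n_landmark_genes + cfg$n_mito_genes + 32L) {
    stop("sim_config: n_genes too small to hold the landmark panel, ",
         "marker genes and mitochondrial genes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  reference: %d drugs x %d cell lines x %d doses, %d landmark genes, %d fp bits\n",
              x$n_drugs, x$n_cell_lines, x$doses_per_drug,
              x$n_landmark_genes, x$n_fp_bits))
  cat(sprintf("  patient:   %d cells x %d genes; fractions: %s\n",
              x$n_cells, x$n_genes,
              paste(sprintf("%s=%.2f", names(x$clone_fractions), x$clone_fractions),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
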