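# Marker panels and mitochondrial symbols embedded in the synthetic patient.
synthetic_tumor_markers <- c("EPCAM", "PAX8", "MUC16", "WFDC2",
                             "KRT8", "KRT18", "CLDN3", "CD24")
synthetic_normal_markers <- c("CD3D", "CD3E", "CD2", "IL7R",
                              "TRAC", "CD8A", "CCL5", "LTB")
mito_gene_names <- function(n) {
  base <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
            "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB")
  paste0("MT-", rep_len(base, n), ifelse(seq_len(n) > length(base), seq_len(n), ""))
}

#' Simulate a clonally structured scRNA-seq patient sample
#'
#' Draws negative-binomial counts for `n_cells` cells split between a
#' normal population and the malignant clones of `cfg$clone_fractions`.
#' Malignant clones carry (i) multiplicative arm-level expression dosage on
#' the genes inside their `cnv_events` (copy ratio times baseline mean),
#' (ii) an expression module matching one drug target class of the
#' reference (clone k is planted with class k's module, scaled by
#' `clone_module_amplitude` and the class responsiveness), and (iii)
#' elevated tumor marker genes. Normal cells express a lymphoid marker
#' panel. A configurable fraction of cells is simulated with an elevated
#' mitochondrial UMI share so QC filtering is exercisable.
#'
#' Landmark genes, marker genes and filler genes are assigned to
#' chromosome arms 1p..11q by a seeded permutation, with positions strictly
#' ordered within each chromosome; mitochondrial genes sit on contig MT and
#' take no part in CNV windowing.
#'
#' @param cfg a [sim_config()]; `clone_fractions` must contain a
#'   `normal` entry (the downstream pipeline requires a normal reference).
#' @param patient_seed optional seed for the patient-level draws (cells,
#'   noise); defaults to `cfg$seed`. The drug/class-level ground truth is
#'   always derived from `cfg$seed`, so several patients can share one
#'   reference database.
#' @return a list with `counts` (sparse genes x cells integer matrix),
#'   `gene_map` (data.frame: gene, chrom, arm, start, is_mito),
#'   and `truth` (per-cell labels, high-mito flags, per-clone matched
#'   target class and CNV events, plus the shared `reference_truth`).
#' @seealso [simulate_reference()], [call_clones()]
#' @export
simulate_patient <- function(cfg, patient_seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(patient_seed)) patient_seed <- cfg$seed
  fr <- cfg$clone_fractions
  if (!"normal" %in% names(fr)) {
    stop("simulate_patient: clone_fractions must include a 'normal' component; ",
         "the clone pipeline needs patient-matched normal cells as reference")
  }
  clones <- setdiff(names(fr), "normal")
  if (length(clones) < 1L) {
    stop("simulate_patient: at least one malignant clone fraction is required")
  }
  if (length(clones) > cfg$n_target_classes) {
    stop("simulate_patient: more clones than drug target classes to match")
  }
  truth <- reference_truth(cfg)
  set.seed(patient_seed + 2L)

  L <- cfg$n_landmark_genes
  n_mito <- cfg$n_mito_genes
  genes <- c(landmark_gene_names(L),
             synthetic_tumor_markers, synthetic_normal_markers)
  n_filler <- cfg$n_genes - length(genes) - n_mito
  genes <- c(genes, sprintf("G%05d", seq_len(n_filler)), mito_gene_names(n_mito))
  n_nuc <- cfg$n_genes - n_mito

  # genome layout: 22 arms, contiguous blocks, genes permuted into slots
  arms <- paste0(rep(1:11, each = 2), c("p", "q"))
  arm_of_slot <- sort(factor(rep(arms, length.out = n_nuc), levels = arms))
  slot_of_gene <- sample.int(n_nuc)  # gene i occupies genome slot slot_of_gene[i]
  gene_arm <- as.character(arm_of_slot)[slot_of_gene]
  gene_chrom <- sub("[pq]$", "", gene_arm)
  # start positions strictly increasing within each chromosome
  start <- integer(n_nuc)
  for (ch in unique(gene_chrom)) {
    i <- which(gene_chrom == ch)
    start[i] <- rank(slot_of_gene[i]) * 1000L
  }
  gene_map <- data.frame(
    gene = genes,
    chrom = c(gene_chrom, rep("MT", n_mito)),
    arm = c(gene_arm, rep(NA_character_, n_mito)),
    start = c(start, seq_len(n_mito) * 100L),
    is_mito = c(rep(FALSE, n_nuc), rep(TRUE, n_mito))
  )

  # baseline expression means and fixed per-gene NB dispersion (log-normal)
  mu0 <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  theta <- stats::rlnorm(cfg$n_genes, meanlog = log(2), sdlog = 0.6)
  marker_idx <- match(c(synthetic_tumor_markers, synthetic_normal_markers), genes)
  mu0[marker_idx] <- 3  # markers moderately expressed where "on"
  # mitochondrial share set to mito_baseline_frac of total counts
  mito_idx <- which(gene_map$is_mito)
  mu0[mito_idx] <- cfg$mito_baseline_frac / (1 - cfg$mito_baseline_frac) *
    sum(mu0[-mito_idx]) / n_mito
  # mitochondrial transcripts: abundant housekeeping products with little
  # cell-to-cell biological variability, so near-Poisson counts
  theta[mito_idx] <- 50

  tum_idx <- match(synthetic_tumor_markers, genes)
  nor_idx <- match(synthetic_normal_markers, genes)

  # group-level mean vectors: normal + one per clone
  groups <- c("normal", clones)
  mu_group <- matrix(rep(mu0, length(groups)), ncol = length(groups),
                     dimnames = list(genes, groups))
  mu_group[tum_idx, "normal"] <- mu0[tum_idx] * 0.1
  mu_group[nor_idx, "normal"] <- mu0[nor_idx] * 6
  clone_class <- stats::setNames(seq_along(clones), clones)
  for (cl in clones) {
    mu_group[tum_idx, cl] <- mu0[tum_idx] * 6
    mu_group[nor_idx, cl] <- mu0[nor_idx] * 0.1
    # planted drug-class module (log2-scale effects)
    k <- clone_class[[cl]]
    m <- truth$modules[[k]]
    amp <- cfg$clone_module_amplitude * truth$responsiveness[k]
    gi <- match(m$gene, genes)
    mu_group[gi, cl] <- mu_group[gi, cl] * 2^(amp * m$effect)
    # arm-level CNV dosage
    for (ev in cfg$cnv_events[[cl]]) {
      on_arm <- which(!is.na(gene_map$arm) & gene_map$arm == ev$arm)
      mu_group[on_arm, cl] <- mu_group[on_arm, cl] * ev$ratio
    }
  }

  label <- sample(names(fr), cfg$n_cells, replace = TRUE, prob = fr)
  size_factor <- stats::rlnorm(cfg$n_cells, 0, 0.3)
  n_high <- round(cfg$high_mito_fraction * cfg$n_cells)
  high_mito <- rep(FALSE, cfg$n_cells)
  if (n_high > 0) high_mito[sample.int(cfg$n_cells, n_high)] <- TRUE

  mu <- mu_group[, label, drop = FALSE] *
    matrix(size_factor, cfg$n_genes, cfg$n_cells, byrow = TRUE)
  if (any(high_mito)) {
    boost <- (cfg$high_mito_level / (1 - cfg$high_mito_level)) /
      (cfg$mito_baseline_frac / (1 - cfg$mito_baseline_frac))
    mu[mito_idx, high_mito] <- mu[mito_idx, high_mito] * boost
  }
  counts <- matrix(
    stats::rnbinom(length(mu), size = rep(theta, cfg$n_cells), mu = as.vector(mu)),
    nrow = cfg$n_genes, ncol = cfg$n_cells,
    dimnames = list(genes, sprintf("cell_%04d", seq_len(cfg$n_cells)))
  )
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  list(
    counts = counts,
    gene_map = gene_map,
    truth = list(
      cell_labels = stats::setNames(label, colnames(counts)),
      high_mito = stats::setNames(high_mito, colnames(counts)),
      clone_matched_class = clone_class,
      cnv_events = cfg$cnv_events[clones],
      reference = truth
    )
  )
}
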