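make_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

test_that("QC removes cells by detected genes and mitochondrial fraction", {
  m <- make_counts(rbind(matrix(5, 4, 3), c(1, 3, 30)),
                   genes = c("a", "b", "c", "d", "MT-ND1"))
  # mito fractions: 1/21 = 0.048, 3/23 = 0.130, 30/50 = 0.6
  out <- qc_filter(m, min_genes = 0, max_genes = Inf, max_mito_frac = 0.10)
  expect_equal(colnames(out), "c1")
  # organoid-style 20% cutoff keeps a 13%-fraction cell
  m2 <- make_counts(rbind(matrix(10, 4, 1), 6),
                    genes = c("a", "b", "c", "d", "MT-ND1"))
  expect_equal(ncol(qc_filter(m2, 0, Inf, 0.20)), 1L)
  expect_error(qc_filter(m2, 0, Inf, 0.05), "AllCellsRemoved")
  # identity bounds keep everything
  expect_equal(ncol(qc_filter(m, 0, Inf, 1)), 3L)
  # exact-boundary mito fraction is retained (strictly-above rule)
  m3 <- make_counts(rbind(matrix(3, 3, 1), 1),
                    genes = c("a", "b", "c", "MT-ND1"))
  expect_equal(ncol(qc_filter(m3, 0, Inf, 0.10)), 1L)
})

test_that("lognormalize matches the closed form and is depth-invariant", {
  m <- make_counts(matrix(c(100, 400, 9500, 2, 3, 5), 3, 2))
  norm <- lognormalize(m, scale = 1e4)
  expect_equal(norm[, 1], log1p(c(100, 400, 9500)),
               ignore_attr = TRUE)  # cell 1 totals exactly 1e4
  expect_equal(norm[, 2], log1p(1e4 * c(2, 3, 5) / 10), ignore_attr = TRUE)
  doubled <- m
  doubled[, 2] <- m[, 2] * 2
  expect_equal(lognormalize(doubled)[, 2], norm[, 2])
  zero <- make_counts(matrix(c(1, 0), 1, 2))
  expect_error(lognormalize(zero), "ZeroCell")
})

test_that("clustering separates planted blobs and is reproducible", {
  set.seed(42)
  n <- 60
  blob <- function(lams) matrix(rpois(50 * n, lambda = lams), 50, n)
  m <- make_counts(cbind(blob(rep(c(20, 1), each = 25)),
                         blob(rep(c(1, 20), each = 25))),
                   cells = sprintf("c%d", 1:(2 * n)))
  norm <- lognormalize(m)
  cl <- cluster_cells(norm, n_hvg = 50, n_pcs = 5, seed = 1,
                      resolution = 0.5)
  truth <- rep(c(1, 2), each = n)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(ari(cl, truth), 1.0)
  expect_identical(cl, cluster_cells(norm, n_hvg = 50, n_pcs = 5, seed = 1,
                                     resolution = 0.5))
  # identical cells collapse to a single cluster
  same <- make_counts(matrix(4, 30, 60))
  expect_equal(unique(cluster_cells(lognormalize(same))), 1L)
})

test_that("marker scoring labels clusters, weighs shared markers to zero, and flags low signal", {
  set.seed(7)
  n <- 40
  genes <- c("TM1", "TM2", "NM1", "NM2", "SHARED", sprintf("f%d", 1:20))
  base <- matrix(rpois(25 * 2 * n, 2), 25, 2 * n)
  base[1:2, 1:n] <- base[1:2, 1:n] + 20          # tumor markers up in cells 1..n
  base[3:4, (n + 1):(2 * n)] <- base[3:4, (n + 1):(2 * n)] + 20
  m <- make_counts(base, genes = genes)
  norm <- lognormalize(m)
  clusters <- stats::setNames(rep(c(1L, 2L), each = n), colnames(m))
  db <- data.frame(
    cell_type = c("Tumor", "Tumor", "Tumor", "Normal", "Normal", "Normal"),
    gene = c("TM1", "TM2", "SHARED", "NM1", "NM2", "SHARED"),
    direction = 1,
    is_malignant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  res <- marker_score(norm, clusters, db)
  expect_equal(res$cell_type[res$cluster == 1], "Tumor")
  expect_equal(res$cell_type[res$cluster == 2], "Normal")
  # a marker present in every cell type carries zero weight
  expect_equal(as.numeric(attr(res, "weights")["SHARED"]), 0)
  # cluster with no marker signal falls below the n/4 rule -> Unknown
  noise <- make_counts(matrix(rpois(25 * n, 2), 25, n), genes = genes)
  res2 <- marker_score(lognormalize(noise),
                       stats::setNames(rep(1L, n), colnames(noise)), db)
  expect_equal(res2$cell_type, "Unknown")
  expect_error(marker_score(norm, clusters,
                            data.frame(cell_type = "X", gene = "absent")),
               "NoMarkersFound")
})

test_that("CNV profiles are reference-centred, smoothed and winsorized", {
  pat <- simulate_patient(sim_config(seed = 21, n_cells = 300))
  norm <- lognormalize(qc_filter(pat$counts, 0, Inf, 1))
  truth <- pat$truth$cell_labels[colnames(norm)]
  ref <- names(truth)[truth == "normal"]
  cnv <- infer_cnv_profiles(norm, ref, pat$gene_map, window = 21)
  # normal reference cells: mean-zero profiles, arm means inside 3 ref SD
  ref_arm <- cnv$arm_means[, ref]
  expect_lt(max(abs(colMeans(cnv$profile[, ref]))), 0.05)
  expect_lt(max(abs(rowMeans(ref_arm))), 3 * cnv$ref_sd)
  expect_lt(max(abs(cnv$profile)), 3 * cnv$ref_sd + 1e-12)
  # planted 1p gain: positive 1p arm mean in >= 90% of clone A cells
  a_cells <- names(truth)[truth == "A"]
  expect_gte(mean(cnv$arm_means["1p", a_cells] > 0), 0.9)
  # planted 7q loss: negative 7q arm mean in >= 90% of clone B cells
  b_cells <- names(truth)[truth == "B"]
  expect_gte(mean(cnv$arm_means["7q", b_cells] < 0), 0.9)
  expect_error(infer_cnv_profiles(norm, ref[1:5], pat$gene_map), "NoReference")
  expect_error(infer_cnv_profiles(norm, character(), pat$gene_map),
               "NoReference")
})

test_that("window = 1 reproduces centred expression up to winsorization", {
  pat <- simulate_patient(tiny_cfg(seed = 31))
  norm <- lognormalize(qc_filter(pat$counts, 0, Inf, 1))
  truth <- pat$truth$cell_labels[colnames(norm)]
  ref <- names(truth)[truth == "normal"]
  cnv1 <- infer_cnv_profiles(norm, ref, pat$gene_map, window = 1)
  gm <- pat$gene_map[!is.na(pat$gene_map$arm), ]
  expect_true(all(cnv1$genes %in% gm$gene))
  # width-1 smoothing is the identity: gene-level noise is untouched, so
  # profiles are rougher than under a 21-gene window, with identical
  # per-cell means before winsorization
  cnv21 <- infer_cnv_profiles(norm, ref, pat$gene_map, window = 21)
  expect_false(isTRUE(all.equal(cnv1$profile, cnv21$profile)))
  expect_gt(stats::sd(cnv1$profile), stats::sd(cnv21$profile))
  expect_error(infer_cnv_profiles(norm, ref, pat$gene_map, window = 20),
               "odd")
})

test_that("majority vote is symmetric and follows the 2-of-3 rule", {
  m <- c(TRUE, FALSE, TRUE, NA)
  s <- c(TRUE, FALSE, FALSE, TRUE)
  c3 <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(call_malignant_ensemble(m, s, c3),
               c(TRUE, FALSE, TRUE, TRUE))
  # permuting the classifiers leaves the consensus unchanged
  expect_equal(call_malignant_ensemble(s, c3, m),
               call_malignant_ensemble(m, s, c3))
  expect_equal(call_malignant_ensemble(c3, m, s),
               call_malignant_ensemble(m, s, c3))
})

test_that("subclone detection recovers planted clones and conserves fractions", {
  pat <- simulate_patient(sim_config(seed = 17, n_cells = 500))
  norm <- lognormalize(qc_filter(pat$counts, 0, Inf, 1))
  truth <- pat$truth$cell_labels[colnames(norm)]
  ref <- names(truth)[truth == "normal"]
  cnv <- infer_cnv_profiles(norm, ref, pat$gene_map, window = 21)
  mal <- names(truth)[truth != "normal"]
  sc <- detect_subclones(cnv, mal)
  expect_false(sc$degenerate)
  expect_equal(sum(sc$fractions), 1)
  expect_gte(ari(truth[mal], as.character(sc$subclone[mal])), 0.9)
  expect_match(sc$newick, "^\\(.*\\);$")
  expect_error(detect_subclones(cnv, mal[1:10]), "TooFewMalignantCells")
})

test_that("a homogeneous malignant population yields a degenerate split", {
  cfg <- sim_config(seed = 23, n_cells = 400,
                    clone_fractions = c(normal = 0.5, A = 0.5),
                    cnv_events = list(A = list(list(arm = "1p", ratio = 1.5),
                                               list(arm = "3p", ratio = 0.5))))
  pat <- simulate_patient(cfg)
  norm <- lognormalize(qc_filter(pat$counts, 0, Inf, 1))
  truth <- pat$truth$cell_labels[colnames(norm)]
  cnv <- infer_cnv_profiles(norm, names(truth)[truth == "normal"],
                            pat$gene_map, window = 21)
  sc <- detect_subclones(cnv, names(truth)[truth == "A"])
  expect_true(sc$degenerate)
  expect_gte(max(sc$fractions), 1 - 0.05)
})

test_that("signatures are antisymmetric, filtered, and detect planted effects", {
  set.seed(5)
  n <- 200
  m <- matrix(rnbinom(300 * 2 * n, mu = 3, size = 2), 300, 2 * n)
  m[7, 1:n] <- rnbinom(n, mu = 6, size = 2)  # planted 2-fold up-regulation
  counts <- make_counts(m)
  norm <- lognormalize(counts)
  g1 <- colnames(counts)[1:n]
  g2 <- colnames(counts)[(n + 1):(2 * n)]
  sig <- compute_signature(norm, g1, g2)
  sig_rev <- compute_signature(norm, g2, g1)
  expect_equal(sig$avg_log2FC, -sig_rev$avg_log2FC)
  expect_true(sig$tested[7])
  expect_lt(sig$p_val_adj[7], 0.05)
  expect_equal(sig$avg_log2FC[7], 1, tolerance = 0.35)
  # identical groups: all fold changes zero, nothing survives the filters
  same <- compute_signature(norm, g1, g1)
  expect_equal(max(abs(same$avg_log2FC)), 0)
  expect_equal(sum(same$tested), 0L)
  expect_error(compute_signature(norm, g1[1:2], g2), "GroupTooSmall")
})

test_that("landmark mapping keeps filtered landmark genes and zeros the rest", {
  sig <- data.frame(gene = c("LM0001", "LM0002", "OTHER"),
                    avg_log2FC = c(1.5, 0.1, 2),
                    pct_1 = 1, pct_2 = 1, p_val = 0.01, p_val_adj = 0.02,
                    tested = c(TRUE, FALSE, TRUE))
  v <- landmark_signature(sig, c("LM0001", "LM0002", "LM0003"))
  expect_equal(as.numeric(v), c(1.5, 0, 0))
})

test_that("the full pipeline calls malignancy and subclones on a synthetic patient", {
  pat <- simulate_patient(sim_config(seed = 3, high_mito_fraction = 0.05))
  cm <- call_clones(pat$counts, pat$gene_map, seed = 1)
  truth <- pat$truth$cell_labels[cm$cells$barcode]
  sens <- mean(cm$cells$malignant[truth != "normal"])
  spec <- mean(!cm$cells$malignant[truth == "normal"])
  expect_gte((sens + spec) / 2, 0.9)
  expect_equal(cm$mode, "combination")
  expect_named(cm$signatures, c("A", "B"))
  # subclone fractions over malignant cells sum to one
  expect_equal(sum(cm$subclones$fractions), 1)
})

test_that("low malignant fractions trigger monotherapy mode", {
  cfg <- sim_config(seed = 29, n_cells = 700,
                    clone_fractions = c(normal = 0.95, A = 0.05),
                    cnv_events = list(A = list(list(arm = "1p", ratio = 1.5),
                                               list(arm = "3p", ratio = 0.5))))
  pat <- simulate_patient(cfg)
  cm <- call_clones(pat$counts, pat$gene_map, seed = 1)
  expect_equal(cm$mode, "monotherapy")
  expect_true("malignant" %in% names(cm$signatures) ||
                length(cm$signatures) == 0)
})
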