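#' Quality-control cell filtering
#'
#' Removes cells with too few or too many detected genes, or with a
#' mitochondrial UMI fraction above `max_mito_frac` (strictly above: a
#' cell at exactly the cutoff is retained). Mitochondrial genes are
#' identified by the `MT-` symbol prefix (case-insensitive).
#'
#' @param counts sparse or dense genes x cells count matrix with gene
#'   symbols as rownames.
#' @param min_genes,max_genes detected-gene bounds (inclusive).
#' @param max_mito_frac maximum mitochondrial UMI fraction (0.1 for fresh
#'   samples; 0.2 is customary for organoids).
#' @return the column-filtered matrix; `attr(, "qc_report")` holds
#'   per-cell metrics and removal reasons.
#' @export
qc_filter <- function(counts, min_genes = 200, max_genes = 6000,
                      max_mito_frac = 0.1) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  mito <- grepl("^MT-", rownames(counts), ignore.case = TRUE)
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_frac <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(counts))
  keep <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  report <- data.frame(
    barcode = colnames(counts),
    total_counts = as.numeric(totals),
    detected_genes = as.numeric(detected),
    mito_frac = as.numeric(mito_frac),
    pass = keep,
    row.names = NULL
  )
  if (!any(keep)) {
    stop("AllCellsRemoved: no cell passed QC (bounds: genes in [",
         min_genes, ", ", max_genes, "], mito <= ", max_mito_frac, ")")
  }
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Log-normalize counts
#'
#' Per cell, counts are scaled to `scale` total and transformed with
#' `log(1 + x)` (the LogNormalize convention). Invariant to per-cell
#' depth: doubling all counts of a cell leaves its normalized vector
#' unchanged.
#'
#' @param counts genes x cells count matrix (sparse supported).
#' @param scale target per-cell total after scaling.
#' @return genes x cells matrix of normalized expression, same class
#'   family as the input.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop("ZeroCell: ", sum(totals == 0), " cell(s) with zero total counts; ",
         "run qc_filter first")
  }
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / totals)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    methods::as(out, "CsparseMatrix")
  } else {
    log1p(sweep(counts, 2, scale / totals, `*`))
  }
}

# row variances of a (possibly sparse) matrix without densifying
row_vars <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Cluster cells by community detection
#'
#' Standard graph-based clustering: top variable genes, per-gene scaling,
#' PCA, a shared-nearest-neighbour graph (Jaccard weights over the k
#' nearest neighbours in PC space), and Louvain community detection.
#' Deterministic under a fixed seed.
#'
#' @param normalized genes x cells log-normalized matrix (>= 50 cells).
#' @param n_hvg number of highly variable genes used.
#' @param n_pcs number of principal components.
#' @param k neighbours per cell for the SNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return integer cluster labels named by cell barcode.
#' @export
cluster_cells <- function(normalized, n_hvg = 1000, n_pcs = 20, k = 15,
                          resolution = 1, seed = 1L) {
  n <- ncol(normalized)
  stopifnot(n >= 50)
  set.seed(seed)
  v <- row_vars(normalized)
  if (all(v < 1e-12)) {
    # identical cells: a single community
    return(stats::setNames(rep(1L, n), colnames(normalized)))
  }
  hvg <- utils::head(order(v, decreasing = TRUE), min(n_hvg, sum(v > 1e-12)))
  x <- t(as.matrix(normalized[hvg, , drop = FALSE]))
  x <- scale(x)
  x[x > 10] <- 10  # cap extreme standardized values
  n_pcs <- min(n_pcs, ncol(x) - 1L, n - 1L)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  d <- as.matrix(stats::dist(pcs))
  k <- min(k, n - 1L)
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1L)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)            # |N(i) intersect N(j)|
  jac <- methods::as(shared, "TsparseMatrix")
  wt <- jac@x / (2 * k - jac@x)               # Jaccard on k-sets
  keep <- wt > 1 / 15 & jac@i < jac@j         # prune weak edges, upper triangle
  g <- igraph::graph_from_data_frame(
    data.frame(from = jac@i[keep] + 1L, to = jac@j[keep] + 1L,
               weight = wt[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(cl)), colnames(normalized))
}

#' Built-in marker database
#'
#' Small marker panels for the supported modes: `"synthetic"` matches the
#' marker genes planted by [simulate_patient()]; `"aml"` carries the
#' classical blast panel (CD33, CD34, CD38, PROM1, ENG, CD99, KIT) with T
#' cells as the known-normal anchor; `"hgsc"` carries the PAX8+ tumor
#' panel (PAX8, MUC16, WFDC2, EPCAM) against stromal/lymphoid markers.
#'
#' @param mode one of `"synthetic"`, `"aml"`, `"hgsc"`.
#' @return data.frame with columns `cell_type`, `gene`, `direction`
#'   (+1 positive / -1 negative marker) and `is_malignant`.
#' @export
default_marker_db <- function(mode = c("synthetic", "aml", "hgsc")) {
  mode <- match.arg(mode)
  mk <- function(type, genes, malignant, direction = 1) {
    data.frame(cell_type = type, gene = genes, direction = direction,
               is_malignant = malignant)
  }
  switch(mode,
    synthetic = rbind(
      mk("Normal lymphoid", synthetic_normal_markers, FALSE),
      mk("Malignant epithelial", synthetic_tumor_markers, TRUE)
    ),
    aml = rbind(
      mk("T cell", c("CD3D", "CD3E", "CD2", "IL7R", "TRAC", "CD8A"), FALSE),
      mk("Blast", c("CD33", "CD34", "CD38", "PROM1", "ENG", "CD99", "KIT"), TRUE)
    ),
    hgsc = rbind(
      mk("Stromal/lymphoid", c("COL1A1", "DCN", "PDGFRB", "CD3D", "CD3E", "PTPRC"),
         FALSE),
      mk("PAX8+ tumor", c("PAX8", "MUC16", "WFDC2", "EPCAM", "KRT8", "KRT18"),
         TRUE)
    )
  )
}

#' Marker-based cell-type scoring of clusters
#'
#' Specificity-weighted marker scoring: per-gene weights decrease linearly
#' with the number of cell types sharing the marker (a marker listed for
#' every type gets weight 0). Per cell, each type scores the weighted sum
#' of standardized expression of its positive markers minus its negative
#' markers, scaled by `1/sqrt(n_markers)`; per-cluster scores are the sum
#' over member cells. A cluster whose best score falls below
#' `n_cells_in_cluster / 4` is labeled `"Unknown"`.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param clusters integer cluster labels named by barcode.
#' @param marker_db data.frame as in [default_marker_db()].
#' @return data.frame per cluster: `cluster`, `cell_type`, `score`,
#'   `n_cells`; the full cluster-by-type score matrix is in
#'   `attr(, "scores")`, per-gene weights in `attr(, "weights")`.
#' @export
marker_score <- function(normalized, clusters, marker_db) {
  stopifnot(all(c("cell_type", "gene") %in% names(marker_db)))
  if (is.null(marker_db$direction)) marker_db$direction <- 1
  marker_db <- marker_db[marker_db$gene %in% rownames(normalized), , drop = FALSE]
  if (nrow(marker_db) == 0L) {
    stop("NoMarkersFound: no marker gene is present in the matrix")
  }
  types <- unique(marker_db$cell_type)
  n_types <- length(types)
  shared <- tapply(marker_db$cell_type, marker_db$gene,
                   function(t) length(unique(t)))
  w <- if (n_types > 1) 1 - (shared - 1) / (n_types - 1) else rep(1, length(shared))

  genes <- unique(marker_db$gene)
  x <- as.matrix(normalized[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  cell_scores <- matrix(0, n_types, ncol(normalized),
                        dimnames = list(types, colnames(normalized)))
  for (t in types) {
    sub <- marker_db[marker_db$cell_type == t, ]
    wt <- as.numeric(w[sub$gene]) * sub$direction
    zs <- z[sub$gene, , drop = FALSE] * wt
    cell_scores[t, ] <- colSums(zs) / sqrt(nrow(sub))
  }
  cl_ids <- sort(unique(clusters))
  scores <- t(vapply(cl_ids, function(ci) {
    rowSums(cell_scores[, clusters == ci, drop = FALSE])
  }, numeric(n_types)))
  rownames(scores) <- cl_ids
  n_cells <- as.integer(table(clusters)[as.character(cl_ids)])
  best <- apply(scores, 1, which.max)
  label <- types[best]
  top <- scores[cbind(seq_along(cl_ids), best)]
  label[top < n_cells / 4] <- "Unknown"
  out <- data.frame(cluster = cl_ids, cell_type = label,
                    score = top, n_cells = n_cells, row.names = NULL)
  attr(out, "scores") <- scores
  attr(out, "weights") <- w
  out
}

# chromosome ordering helper: numeric chromosomes first, in numeric order
chrom_order <- function(chrom, start) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, start)
}

running_mean <- function(v, window) {
  if (window <= 1L || length(v) == 1L) return(v)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Infer per-cell CNV profiles from expression
#'
#' Expression-derived copy-number proxy: genes expressed below
#' `expr_cutoff` (mean normalized expression) are dropped; each cell's
#' expression is centred on the normal-reference gene means; a moving
#' average of odd width `window` smooths the centred values along genome
#' order within each chromosome; values are winsorized to three standard
#' deviations of the reference-cell distribution; and arm-level segment
#' means are emitted. By construction the reference cells' profiles are
#' mean-zero.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param reference_cells barcodes of designated normal cells (>= 20).
#' @param gene_map data.frame with `gene`, `chrom`, `arm`, `start`; genes
#'   without an arm (e.g. mitochondrial) are ignored.
#' @param window odd moving-average width in genes.
#' @param expr_cutoff minimum mean normalized expression for a gene to
#'   enter the profile.
#' @return a `cnv_profiles` list: `profile` (retained genes x cells),
#'   `arm_means` (arms x cells), `genes`, `arms` (per retained gene),
#'   `reference_cells`, `ref_sd`, `window`.
#' @export
infer_cnv_profiles <- function(normalized, reference_cells, gene_map,
                               window = 101L, expr_cutoff = 0.1) {
  if (length(reference_cells) == 0 ||
      !all(reference_cells %in% colnames(normalized))) {
    stop("NoReference: normal reference cells missing from the matrix")
  }
  if (length(reference_cells) < 20L) {
    stop("NoReference: need >= 20 normal reference cells, got ",
         length(reference_cells))
  }
  if (window %% 2L == 0L) stop("infer_cnv_profiles: window must be odd")
  gm <- gene_map[!is.na(gene_map$arm) & gene_map$gene %in% rownames(normalized), ]
  gm <- gm[chrom_order(gm$chrom, gm$start), ]
  keep <- Matrix::rowMeans(normalized[gm$gene, , drop = FALSE]) >= expr_cutoff
  gm <- gm[keep, , drop = FALSE]
  if (nrow(gm) == 0L) stop("infer_cnv_profiles: no gene passes expr_cutoff")

  e <- as.matrix(normalized[gm$gene, , drop = FALSE])
  # centre each gene on its depth-conditional reference expectation
  # (quadratic in log depth): log1p-normalized expression drifts with
  # sequencing depth, and a flat reference mean would turn depth
  # differences into spurious CNV shifts
  depth <- log10(Matrix::colSums(normalized > 0) + 1)
  dc <- depth - mean(depth[reference_cells])
  xr <- cbind(1, dc[reference_cells], dc[reference_cells]^2)
  er <- e[, reference_cells, drop = FALSE]
  beta <- er %*% xr %*% solve(crossprod(xr))
  e <- e - beta %*% t(cbind(1, dc, dc^2))
  # per-cell mean centring removes residual library-composition offsets
  # (the median is pinned by the zero-count mode in shallow cells)
  e <- sweep(e, 2, colMeans(e))
  smoothed <- e
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    smoothed[i, ] <- apply(e[i, , drop = FALSE], 2, running_mean,
                           window = window)
  }
  ref_sd <- stats::sd(smoothed[, reference_cells])
  lim <- 3 * ref_sd
  smoothed[smoothed > lim] <- lim
  smoothed[smoothed < -lim] <- -lim

  arm_means <- rowsum(smoothed, gm$arm) / as.vector(table(gm$arm)[
    sort(unique(gm$arm))])
  structure(
    list(profile = smoothed, arm_means = arm_means, genes = gm$gene,
         arms = gm$arm, reference_cells = reference_cells,
         ref_sd = ref_sd, window = as.integer(window),
         depth = stats::setNames(as.numeric(depth), colnames(e))),
    class = "cnv_profiles"
  )
}

#' Aneuploidy-score votes from CNV profiles
#'
#' Cells are grouped by Ward clustering on arm-level CNV means
#' (`n_groups` clades); each clade's aneuploidy score is the mean squared
#' arm mean of its centroid, and the clade is called aneuploid when its
#' score exceeds the `null_quantile` of a bootstrap null built from
#' equal-sized, depth-matched draws of the designated reference cells
#' (each member cell is matched by a reference cell of similar depth, so
#' residual depth trends inflate the null rather than the calls).
#' Clade-level pooling mirrors segmentation-based callers: at realistic
#' expression noise a single cell's arm means are only a few SD away
#' from zero, so per-cell thresholding cannot be both sensitive and
#' specific.
#'
#' @param cnv a [infer_cnv_profiles()] result.
#' @param n_groups clades used for pooling (capped at the cell count).
#' @param null_quantile quantile of the bootstrap reference null used as
#'   the calling threshold.
#' @param n_boot bootstrap draws per clade size.
#' @param seed integer seed for the bootstrap.
#' @return logical vector (TRUE = aneuploid call) named by barcode.
#' @export
aneuploidy_votes <- function(cnv, n_groups = 6L, null_quantile = 0.99,
                             n_boot = 200L, seed = 1L) {
  am <- cnv$arm_means
  n <- ncol(am)
  n_groups <- min(n_groups, n)
  hc <- stats::hclust(stats::dist(t(am)), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_groups)
  set.seed(seed)
  ref <- cnv$reference_cells
  k_match <- min(25L, length(ref))
  # reference cells ranked by depth distance to each cell, for matching
  ref_depth <- cnv$depth[ref]
  vote <- stats::setNames(rep(FALSE, n), colnames(am))
  for (ci in unique(cl)) {
    cells <- colnames(am)[cl == ci]
    score <- mean(rowMeans(am[, cells, drop = FALSE])^2)
    pool <- lapply(cells, function(cc) {
      ref[utils::head(order(abs(ref_depth - cnv$depth[cc])), k_match)]
    })
    null <- replicate(n_boot, {
      draw <- vapply(pool, function(p) sample(p, 1L), character(1))
      mean(rowMeans(am[, draw, drop = FALSE])^2)
    })
    if (score > stats::quantile(null, null_quantile, names = FALSE)) {
      vote[cells] <- TRUE
    }
  }
  vote
}

#' Two-way CNV clustering votes
#'
#' k-means (k = 2) on arm-level CNV means; the cluster whose centroid is
#' nearest zero is called diploid, the other aneuploid.
#'
#' @param cnv a [infer_cnv_profiles()] result.
#' @param seed integer seed for k-means initialization.
#' @return logical vector (TRUE = aneuploid cluster) named by barcode.
#' @export
cnv_cluster_votes <- function(cnv, seed = 1L) {
  x <- t(cnv$arm_means)
  if (all(apply(x, 2, stats::sd) < 1e-12)) {
    return(stats::setNames(rep(FALSE, nrow(x)), rownames(x)))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = 2L, nstart = 10L)
  aneuploid_cluster <- which.max(rowSums(km$centers^2))
  stats::setNames(km$cluster == aneuploid_cluster, rownames(x))
}

#' Majority-vote consensus of three malignancy classifiers
#'
#' A cell is called malignant when at least two of the three votes are
#' malignant; `NA` votes count as normal. Symmetric in its arguments.
#'
#' @param marker_vote,cnv_score_vote,cnv_cluster_vote logical vectors over
#'   the same cells.
#' @return logical vector: TRUE = consensus malignant.
#' @export
call_malignant_ensemble <- function(marker_vote, cnv_score_vote,
                                    cnv_cluster_vote) {
  stopifnot(length(marker_vote) == length(cnv_score_vote),
            length(marker_vote) == length(cnv_cluster_vote))
  v <- cbind(marker_vote, cnv_score_vote, cnv_cluster_vote)
  v[is.na(v)] <- FALSE
  out <- rowSums(v) >= 2L
  names(out) <- names(marker_vote)
  out
}

#' Detect two broad subclones among malignant cells
#'
#' Ward-linkage hierarchical clustering (Euclidean distance on arm-level
#' CNV means) cut into `k` clades. A split only counts when the top merge
#' height exceeds twice the next merge height (a homogeneous population
#' merges at near-constant heights); otherwise the population is a single
#' clade and the result is flagged degenerate. Clades below
#' `min_fraction` of the malignant cells are labeled `"minor"`; of the
#' remaining clades the two largest become subclones A and B (size ties
#' broken by the lower mean intra-clade distance). With fewer than two
#' major clades the result is flagged degenerate (the caller should fall
#' back to monotherapy mode).
#' A Newick tree with branch lengths proportional to clone fractions is
#' attached.
#'
#' @param cnv a [infer_cnv_profiles()] result.
#' @param malignant_cells barcodes of consensus-malignant cells (>= 40).
#' @param k number of clades to cut.
#' @param min_fraction minimum malignant-cell fraction of a major clade.
#' @return a list: `subclone` (factor A/B/minor per malignant cell),
#'   `fractions` (named, summing to 1 over malignant cells), `degenerate`,
#'   `newick`, `hclust`.
#' @export
detect_subclones <- function(cnv, malignant_cells, k = 2L,
                             min_fraction = 0.05) {
  if (length(malignant_cells) < 40L) {
    stop("TooFewMalignantCells: need >= 40, got ", length(malignant_cells))
  }
  x <- t(cnv$arm_means[, malignant_cells, drop = FALSE])
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  h <- sort(hc$height, decreasing = TRUE)
  # a genuine two-clade structure towers over the within-clade merges;
  # a homogeneous population merges at near-constant heights
  split_ratio <- if (length(h) >= 2L) h[1] / h[2] else Inf
  if (split_ratio < 2) {
    subclone <- stats::setNames(
      factor(rep("A", length(malignant_cells)),
             levels = c("A", "B", "minor")), malignant_cells)
    fr <- c(A = 1, B = 0, minor = 0)
    return(list(subclone = subclone, fractions = fr, degenerate = TRUE,
                newick = "(A:1.0000);", hclust = hc,
                split_ratio = split_ratio))
  }
  cl <- stats::cutree(hc, k = k)
  sizes <- table(cl)
  frac <- as.numeric(sizes) / length(malignant_cells)
  ids <- as.integer(names(sizes))
  major <- ids[frac >= min_fraction]
  # tie-break equally sized clades by mean intra-clade distance
  intra <- vapply(ids, function(ci) {
    m <- x[cl == ci, , drop = FALSE]
    if (nrow(m) < 2) return(0)
    mean(stats::dist(m))
  }, numeric(1))
  ord <- order(-frac[match(major, ids)], intra[match(major, ids)])
  major <- major[ord]

  subclone <- rep("minor", length(malignant_cells))
  degenerate <- length(major) < 2L
  if (length(major) >= 1L) subclone[cl == major[1]] <- "A"
  if (length(major) >= 2L) subclone[cl == major[2]] <- "B"
  subclone <- stats::setNames(factor(subclone, levels = c("A", "B", "minor")),
                              malignant_cells)
  fractions <- table(subclone) / length(malignant_cells)
  present <- fractions[fractions > 0]
  newick <- paste0("(", paste(sprintf("%s:%.4f", names(present),
                                      as.numeric(present)), collapse = ","),
                   ");")
  list(subclone = subclone, fractions = c(fractions), degenerate = degenerate,
       newick = newick, hclust = hc, split_ratio = split_ratio)
}

#' Differential-expression signature of a cell group versus normal cells
#'
#' Per gene: log2 fold change of (mean de-logged expression + 1) between
#' the group and the normal cells, a two-sided Wilcoxon rank-sum p-value,
#' and a Benjamini-Hochberg adjusted q-value. Genes expressed in fewer
#' than `min_pct` of cells in both groups, or with
#' `|log2FC| < min_abs_log2fc`, are excluded from testing and from the
#' signature vector handed to the model.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param cells_group,cells_normal barcodes of the two groups (>= 3 each).
#' @param min_pct minimum expressed fraction in at least one group.
#' @param min_abs_log2fc minimum absolute log2 fold change.
#' @return a `clone_signature` data.frame: `gene`, `avg_log2FC`, `pct_1`,
#'   `pct_2`, `p_val`, `p_val_adj` (NA for untested genes), `tested`.
#' @export
compute_signature <- function(normalized, cells_group, cells_normal,
                              min_pct = 0.1, min_abs_log2fc = 0.25) {
  if (length(cells_group) < 3L || length(cells_normal) < 3L) {
    stop("GroupTooSmall: both groups need >= 3 cells")
  }
  x <- normalized[, cells_group, drop = FALSE]
  y <- normalized[, cells_normal, drop = FALSE]
  pct1 <- Matrix::rowMeans(x > 0)
  pct2 <- Matrix::rowMeans(y > 0)
  m1 <- Matrix::rowMeans(expm1(as.matrix(x)))
  m2 <- Matrix::rowMeans(expm1(as.matrix(y)))
  lfc <- log2(m1 + 1) - log2(m2 + 1)
  tested <- pmax(pct1, pct2) >= min_pct & abs(lfc) >= min_abs_log2fc
  pv <- rep(NA_real_, nrow(normalized))
  xm <- as.matrix(x); ym <- as.matrix(y)
  for (i in which(tested)) {
    pv[i] <- stats::wilcox.test(xm[i, ], ym[i, ], exact = FALSE)$p.value
  }
  qv <- rep(NA_real_, length(pv))
  qv[tested] <- stats::p.adjust(pv[tested], method = "BH")
  out <- data.frame(
    gene = rownames(normalized),
    avg_log2FC = lfc,
    pct_1 = pct1,
    pct_2 = pct2,
    p_val = pv,
    p_val_adj = qv,
    tested = tested,
    row.names = NULL
  )
  class(out) <- c("clone_signature", "data.frame")
  out
}

#' Map a signature to the landmark panel
#'
#' Restricts a [compute_signature()] result to the landmark gene panel:
#' genes passing the expression/fold-change filters contribute their
#' log2 fold change, missing or filtered landmarks are set to 0,
#' non-landmark genes are dropped.
#'
#' @param signature a `clone_signature`.
#' @param landmark_genes character vector defining the panel and order.
#' @return named numeric vector over `landmark_genes`.
#' @export
landmark_signature <- function(signature, landmark_genes) {
  out <- stats::setNames(numeric(length(landmark_genes)), landmark_genes)
  keep <- signature$tested & signature$gene %in% landmark_genes
  out[signature$gene[keep]] <- signature$avg_log2FC[keep]
  out
}

#' Full clone-calling pipeline
#'
#' Runs QC, log-normalization, clustering, marker-based typing, CNV
#' inference against marker-anchored normal reference cells, the
#' three-vote malignancy ensemble, subclone detection and per-clone
#' differential-expression signatures. When the malignant fraction falls
#' below `mono_floor`, fewer than 40 malignant cells are found, or
#' subclone detection is degenerate, the pipeline switches to monotherapy
#' mode with a single pooled malignant signature.
#'
#' @param counts genes x cells count matrix (symbols as rownames).
#' @param gene_map data.frame with `gene`, `chrom`, `arm`, `start`.
#' @param marker_db marker database (see [default_marker_db()]); its
#'   `is_malignant` column anchors the known-normal reference.
#' @param min_genes,max_genes,max_mito_frac QC bounds.
#' @param window,expr_cutoff CNV parameters (see [infer_cnv_profiles()]);
#'   `window = NULL` picks an odd width near a third of the typical arm
#'   gene count, capped at 101.
#' @param k_subclones,min_fraction subclone parameters.
#' @param mono_floor malignant fraction below which monotherapy mode is
#'   selected.
#' @param resolution,seed clustering parameters.
#' @return a `clone_map` list: `cells` (per-cell data.frame with QC flag,
#'   cluster, cell type, the three votes, consensus label and subclone),
#'   `mode` ("combination" or "monotherapy"), `fractions`, `signatures`
#'   (named list of `clone_signature`s: subclones A/B or pooled
#'   "malignant"), `cnv`, `subclones`, `normalized`.
#' @export
call_clones <- function(counts, gene_map,
                        marker_db = default_marker_db("synthetic"),
                        min_genes = 200, max_genes = 6000,
                        max_mito_frac = 0.1,
                        window = NULL, expr_cutoff = 0.1,
                        k_subclones = 2L, min_fraction = 0.05,
                        mono_floor = 0.10,
                        resolution = 1, seed = 1L) {
  filtered <- qc_filter(counts, min_genes, max_genes, max_mito_frac)
  qc_report <- attr(filtered, "qc_report")
  normalized <- lognormalize(filtered)
  clusters <- cluster_cells(normalized, resolution = resolution, seed = seed)
  typing <- marker_score(normalized, clusters, marker_db)

  type_of_cluster <- stats::setNames(typing$cell_type,
                                     as.character(typing$cluster))
  cell_type <- type_of_cluster[as.character(clusters)]
  malignant_types <- unique(marker_db$cell_type[marker_db$is_malignant])
  normal_types <- setdiff(unique(marker_db$cell_type), malignant_types)
  marker_vote <- ifelse(cell_type %in% malignant_types, TRUE,
                        ifelse(cell_type %in% normal_types, FALSE, NA))
  names(marker_vote) <- names(clusters)

  reference_cells <- names(clusters)[cell_type %in% normal_types]
  if (is.null(window)) {
    # about a third of the typical arm gene count, odd, capped at the
    # conventional 101-gene window
    per_arm <- table(gene_map$arm[!is.na(gene_map$arm) &
                                    gene_map$gene %in% rownames(normalized)])
    w <- floor(stats::median(per_arm) / 3)
    window <- max(11L, min(101L, as.integer(w - (1 - w %% 2))))
  }
  cnv <- infer_cnv_profiles(normalized, reference_cells, gene_map,
                            window = window, expr_cutoff = expr_cutoff)
  v_score <- aneuploidy_votes(cnv)
  v_clust <- cnv_cluster_votes(cnv, seed = seed)
  consensus <- call_malignant_ensemble(marker_vote, v_score, v_clust)

  malignant_cells <- names(consensus)[consensus]
  normal_cells <- names(consensus)[!consensus]
  malignant_fraction <- length(malignant_cells) / length(consensus)

  subclones <- NULL
  mode <- "combination"
  if (malignant_fraction < mono_floor || length(malignant_cells) < 40L) {
    mode <- "monotherapy"
  } else {
    subclones <- detect_subclones(cnv, malignant_cells, k = k_subclones,
                                  min_fraction = min_fraction)
    if (subclones$degenerate) mode <- "monotherapy"
  }

  signatures <- list()
  if (mode == "combination") {
    for (cl in c("A", "B")) {
      cells <- names(subclones$subclone)[subclones$subclone == cl]
      signatures[[cl]] <- compute_signature(normalized, cells, normal_cells)
    }
  } else if (length(malignant_cells) >= 3L && length(normal_cells) >= 3L) {
    signatures[["malignant"]] <- compute_signature(normalized,
                                                   malignant_cells,
                                                   normal_cells)
  }

  subclone_col <- rep(NA_character_, length(consensus))
  names(subclone_col) <- names(consensus)
  if (!is.null(subclones)) {
    subclone_col[names(subclones$subclone)] <- as.character(subclones$subclone)
  } else if (length(malignant_cells) > 0) {
    subclone_col[malignant_cells] <- "none"
  }

  cells <- data.frame(
    barcode = names(consensus),
    cluster = as.integer(clusters),
    cell_type = as.character(cell_type),
    marker_vote = as.logical(marker_vote),
    cnv_score_vote = as.logical(v_score),
    cnv_cluster_vote = as.logical(v_clust),
    malignant = as.logical(consensus),
    subclone = subclone_col,
    row.names = NULL
  )
  fractions <- c(malignant = malignant_fraction,
                 normal = 1 - malignant_fraction)
  structure(
    list(cells = cells, qc_report = qc_report, typing = typing,
         mode = mode, fractions = fractions, subclones = subclones,
         signatures = signatures, cnv = cnv, normalized = normalized),
    class = "clone_map"
  )
}

#' @export
print.clone_map <- function(x, ...) {
  cat("<clone_map>\n")
  cat(sprintf("  %d cells passed QC; %.1f%% malignant; mode: %s\n",
              nrow(x$cells), 100 * x$fractions["malignant"], x$mode))
  if (!is.null(x$subclones)) {
    fr <- x$subclones$fractions
    cat("  subclones:", paste(sprintf("%s=%.2f", names(fr), fr),
                              collapse = ", "), "\n")
  }
  invisible(x)
}
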