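#' Write / read the reference database tables
#'
#' CSV round-trip of the perturbation, dose-response and fingerprint
#' tables, plus a JSON ground-truth sidecar when the reference was
#' simulated.
#'
#' @param ref a [simulate_reference()] result (or a list with the same
#'   three tables).
#' @param dir target directory, created if missing.
#' @return `write_reference_db` returns `dir` invisibly;
#'   `read_reference_db` returns a list of the three tables (and `truth`
#'   if the sidecar is present; the sidecar restores only the plain
#'   tabular parts of the truth).
#' @export
write_reference_db <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ref$perturbations, file.path(dir, "perturbations.csv"),
                   row.names = FALSE)
  utils::write.csv(ref$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(ref$fingerprints, file.path(dir, "fingerprints.csv"),
                   row.names = FALSE)
  if (!is.null(ref$truth)) {
    truth <- list(
      landmark_genes = ref$truth$landmark_genes,
      drugs = ref$truth$drugs,
      responsiveness = ref$truth$responsiveness,
      modules = lapply(ref$truth$modules, function(m) m[c("gene", "effect")]),
      perturbation_truth = ref$truth$perturbation_truth
    )
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(dir) {
  out <- list(
    perturbations = utils::read.csv(file.path(dir, "perturbations.csv"),
                                    check.names = FALSE),
    curves = utils::read.csv(file.path(dir, "curves.csv")),
    fingerprints = utils::read.csv(file.path(dir, "fingerprints.csv"),
                                   check.names = FALSE)
  )
  sidecar <- file.path(dir, "ground_truth.json")
  if (file.exists(sidecar)) {
    out$truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  out
}

#' Write / read a 10x-style count matrix triplet
#'
#' `write_counts_mtx` writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` (uncompressed), plus `gene_map.tsv` and a JSON
#' ground-truth sidecar when called on a [simulate_patient()] result.
#' `read_counts_mtx` reads such a directory back into a sparse matrix.
#'
#' @param x a [simulate_patient()] result or a genes x cells matrix.
#' @param dir target directory.
#' @return `write_counts_mtx` returns `dir` invisibly; `read_counts_mtx`
#'   returns a list with `counts` and, when present, `gene_map`.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- if (is.list(x)) x$counts else x
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(counts), symbol = rownames(counts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is.list(x) && !is.null(x$gene_map)) {
    utils::write.table(x$gene_map, file.path(dir, "gene_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(x) && !is.null(x$truth)) {
    jsonlite::write_json(
      list(cell_labels = x$truth$cell_labels,
           high_mito = x$truth$high_mito,
           clone_matched_class = x$truth$clone_matched_class),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  out <- list(counts = m)
  gm <- file.path(dir, "gene_map.tsv")
  if (file.exists(gm)) {
    out$gene_map <- utils::read.table(gm, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  }
  out
}

#' Read a dense CSV count matrix
#'
#' Genes in rows (first column = gene symbol), cells in columns.
#'
#' @param path CSV file path.
#' @return sparse genes x cells matrix.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' Write / read a dose-response combination matrix CSV
#'
#' Layout: first row holds the column-drug doses, first column the
#' row-drug doses, cell \[1,1\] blank; the body is percent inhibition.
#'
#' @param mat a [dose_response_matrix()].
#' @param path CSV file path.
#' @return `write_dose_matrix` returns `path` invisibly;
#'   `read_dose_matrix` returns a `dose_response_matrix`.
#' @export
write_dose_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "dose_response_matrix"))
  body <- rbind(c(NA, mat$col_doses),
                cbind(mat$row_doses, mat$inhibition))
  utils::write.table(body, path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_matrix
#' @export
read_dose_matrix <- function(path) {
  raw <- as.matrix(utils::read.csv(path, header = FALSE))
  dose_response_matrix(
    row_doses = as.numeric(raw[-1, 1]),
    col_doses = as.numeric(raw[1, -1]),
    inhibition = matrix(as.numeric(raw[-1, -1]), nrow = nrow(raw) - 1L)
  )
}
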