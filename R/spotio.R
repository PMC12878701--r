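#' @importFrom utils read.delim write.table head
#' @importFrom methods as
NULL

# ---- gene sets (GMT) -------------------------------------------------------

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene ...`.
#' Duplicate genes within a line are dropped with a warning; a line with
#' fewer than three fields is a parse error naming the line number.
#'
#' @param path path to a GMT file.
#' @return named list of character gene vectors (a gene-set collection),
#'   in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                      i, fields[1], sum(duplicated(genes))), call. = FALSE)
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
  }
  if (any(lengths(sets) == 0))
    stop("GMT contains an empty gene set", call. = FALSE)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- counts (MatrixMarket + index files) -----------------------------------

#' Read a sparse counts matrix (MatrixMarket + index files)
#'
#' @param mtx_path MatrixMarket coordinate file (genes x spots).
#' @param genes_path text file, one gene symbol per line (row index).
#' @param spots_path text file, one spot id per line (column index).
#' @return a `dgCMatrix` with gene/spot dimnames.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, spots_path) {
  m <- Matrix::readMM(mtx_path)
  if (inherits(m, "nMatrix")) m <- m * 1     # pattern file: 1 per entry
  m <- methods::as(m, "CsparseMatrix")
  genes <- readLines(genes_path, warn = FALSE)
  spots <- readLines(spots_path, warn = FALSE)
  if (nrow(m) != length(genes) || ncol(m) != length(spots))
    stop(sprintf(
      "counts dimension mismatch: matrix is %d x %d but index files list %d genes and %d spots",
      nrow(m), ncol(m), length(genes), length(spots)), call. = FALSE)
  if (length(m@x) && any(m@x < 0))
    stop("counts matrix has negative entries", call. = FALSE)
  dimnames(m) <- list(genes, spots)
  m
}

#' Write a sparse counts matrix with its index files
#'
#' @param counts genes x spots matrix (sparse or dense) with dimnames.
#' @param mtx_path,genes_path,spots_path output paths.
#' @export
write_counts_mtx <- function(counts, mtx_path, genes_path, spots_path) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, mtx_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), spots_path)
  invisible(mtx_path)
}

# ---- tables (TSV) ----------------------------------------------------------

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a table as TSV (UTF-8, '.' decimal, no row names)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a spot table
#'
#' Columns: `spot_id`, `x_um`, `y_um`, `donor`, `roi`, `group`, optional
#' `stage`. Spot ids must be unique and coordinates finite.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_spot_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("spot_id", "x_um", "y_um", "donor", "roi", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spot table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$spot_id))
    stop("spot table has duplicated spot_id values", call. = FALSE)
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um)))
    stop("spot table has non-finite coordinates", call. = FALSE)
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  df
}

#' Read and validate per-spot cell-type weights
#'
#' TSV with a `spot_id` column plus one numeric column per cell type.
#' Weights must be nonnegative and each row must sum to 1 within `tol`;
#' offending rows are rejected with their spot id named.
#'
#' @param path TSV path.
#' @param tol tolerance on the row-sum-to-1 invariant.
#' @return data.frame (`spot_id` + one column per cell type).
#' @export
read_celltype_weights <- function(path, tol = 1e-6) {
  df <- .read_tsv(path)
  if (!"spot_id" %in% names(df))
    stop("weights table missing 'spot_id' column", call. = FALSE)
  w <- as.matrix(df[, setdiff(names(df), "spot_id"), drop = FALSE])
  if (!is.numeric(w)) stop("weights columns must be numeric", call. = FALSE)
  if (any(w < 0)) {
    bad <- df$spot_id[which(rowSums(w < 0) > 0)[1]]
    stop("negative cell-type weight at spot ", bad, call. = FALSE)
  }
  dev <- abs(rowSums(w) - 1)
  if (any(dev > tol)) {
    bad <- df$spot_id[dev > tol]
    stop(sprintf("weights do not sum to 1 (tol %g) for %d spot(s), e.g.: %s",
                 tol, length(bad),
                 paste(head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read per-ROI stage labels
#'
#' TSV with columns `roi` and `stage` (early/middle/late).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_stages <- function(path) {
  df <- .read_tsv(path)
  need <- c("roi", "stage")
  if (!all(need %in% names(df)))
    stop("stage table needs columns roi, stage", call. = FALSE)
  ok <- c("early", "middle", "late")
  if (!all(df$stage %in% ok))
    stop("stage labels must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a pipeline configuration (YAML)
#' @param path YAML path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `spots.tsv` (spot table), `weights.tsv`, `counts.mtx` +
#' `genes.tsv` + `barcodes.tsv`, `truth.tsv` (true labels and latent
#' activities) and, for staged ROIs, `stages.tsv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(cohort$spot_table, file.path(dir, "spots.tsv"))
  write_tsv(cohort$weights, file.path(dir, "weights.tsv"))
  write_counts_mtx(cohort$counts, file.path(dir, "counts.mtx"),
                   file.path(dir, "genes.tsv"),
                   file.path(dir, "barcodes.tsv"))
  truth <- cbind(cohort$truth$labels,
                 as.data.frame(cohort$truth$latent, check.names = FALSE))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  st <- unique(cohort$spot_table[!is.na(cohort$spot_table$stage),
                                 c("roi", "stage")])
  if (nrow(st)) write_tsv(st, file.path(dir, "stages.tsv"))
  invisible(dir)
}
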