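#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats median p.adjust rbinom rnbinom rpois runif sd setNames
#'   wilcox.test hclust cutree dist as.dist cophenetic ks.test quantile
#' @importFrom utils read.csv write.csv combn head
NULL

# Canonical human chromosome order; anything else sorts lexically after.
CANONICAL_CHROMS <- c(paste0("chr", 1:22), "chrX", "chrY")

#' Order chromosome names canonically
#'
#' chr1..chr22, chrX, chrY first, then unknown names in lexical order.
#'
#' @param chroms character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @export
chrom_rank <- function(chroms) {
  idx <- match(chroms, CANONICAL_CHROMS)
  unknown <- is.na(idx)
  if (any(unknown)) {
    extra <- sort(unique(chroms[unknown]))
    idx[unknown] <- length(CANONICAL_CHROMS) + match(chroms[unknown], extra)
  }
  idx
}

stop_named <- function(code, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(code, "tfhlscape_error")))
}

#' Validate a gene-by-cell count matrix
#'
#' @param counts a sparse or dense matrix, genes in rows (rownames = symbols),
#'   cells in columns (colnames = barcodes).
#' @return the matrix as `dgCMatrix`, invisibly checked.
#' @export
validate_count_matrix <- function(counts) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_named("count_matrix_error", "count matrix must carry gene and barcode dimnames")
  if (anyDuplicated(colnames(counts)))
    stop_named("count_matrix_error", "duplicate cell barcodes in count matrix")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop_named("count_matrix_error", "counts must be non-negative integers")
  counts
}

#' Read a CellRanger-style MatrixMarket count matrix
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gene symbols in
#' the first column) in `dir`. MTX indices are 1-based on disk.
#'
#' @param dir directory containing the triplet.
#' @return a validated `dgCMatrix`, genes x cells.
#' @export
read_count_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_named("missing_file_error", "missing count matrix file(s): %s",
               paste(basename(missing), collapse = ", "))
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  feats <- read.delim(paths[3], header = FALSE, stringsAsFactors = FALSE)
  genes <- feats[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop_named("dimension_error",
               "matrix is %d x %d but features/barcodes have %d/%d entries",
               nrow(m), ncol(m), length(genes), length(barcodes))
  dimnames(m) <- list(genes, barcodes)
  validate_count_matrix(m)
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @export
write_count_matrix <- function(counts, dir) {
  counts <- validate_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(rownames(counts), rownames(counts), "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

CONTIG_COLUMNS <- c("barcode", "chain", "v_gene", "j_gene",
                    "cdr3", "cdr3_nt", "productive", "umis")
ALLOWED_CHAINS <- c("TRA", "TRB", "IGH", "IGK", "IGL")

#' Read a 10x-style filtered contig annotation CSV
#'
#' `productive` is parsed as TRUE only for "True"/"true"/"TRUE"; anything else
#' (including "None") is FALSE. Row order is preserved.
#'
#' @param path CSV path (gzip transparent).
#' @return data.frame with columns barcode, chain, v_gene, j_gene, cdr3,
#'   cdr3_nt, productive (logical), umis (integer).
#' @export
read_contigs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(CONTIG_COLUMNS, names(df))
  if (length(absent))
    stop_named("missing_column_error", "contig CSV lacks column(s): %s",
               paste(absent, collapse = ", "))
  df <- df[CONTIG_COLUMNS]
  df$productive <- as.character(df$productive) %in% c("True", "true", "TRUE")
  df$umis <- as.integer(df$umis)
  validate_contigs(df)
}

#' @rdname read_contigs
#' @param contigs contig table to validate or write.
#' @export
validate_contigs <- function(contigs) {
  bad <- setdiff(unique(contigs$chain), ALLOWED_CHAINS)
  if (length(bad))
    stop_named("contig_error", "unknown chain(s): %s", paste(bad, collapse = ", "))
  if (any(contigs$productive & (is.na(contigs$cdr3_nt) | contigs$cdr3_nt == "")))
    stop_named("contig_error", "productive contig with empty cdr3_nt")
  contigs
}

#' @rdname read_contigs
#' @export
write_contigs <- function(contigs, path) {
  validate_contigs(contigs)
  out <- contigs[CONTIG_COLUMNS]
  out$productive <- ifelse(out$productive, "True", "False")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell, per-locus read pileup table
#'
#' TSV with columns barcode, locus, ref_reads, alt_reads. A `total` column is
#' derived as ref + alt.
#'
#' @param path TSV path.
#' @return validated data.frame with an added `total` column.
#' @export
read_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "locus", "ref_reads", "alt_reads")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_named("missing_column_error", "pileup lacks column(s): %s",
               paste(absent, collapse = ", "))
  if (any(df$ref_reads < 0) || any(df$alt_reads < 0))
    stop_named("pileup_error", "negative read counts in pileup")
  df$total <- df$ref_reads + df$alt_reads
  df
}

#' @rdname read_pileup
#' @param pileup pileup table.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup[c("barcode", "locus", "ref_reads", "alt_reads")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene genomic-position table
#'
#' TSV with columns gene, chrom, start, end; 1-based inclusive coordinates.
#' Rows are returned sorted by (chromosome, start) in canonical chromosome
#' order.
#'
#' @param path TSV path.
#' @return validated, position-sorted data.frame.
#' @export
read_gene_positions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_named("missing_column_error", "gene positions lack column(s): %s",
               paste(absent, collapse = ", "))
  validate_gene_positions(df)
}

#' @rdname read_gene_positions
#' @param positions gene position table.
#' @export
validate_gene_positions <- function(positions) {
  if (any(positions$start > positions$end))
    stop_named("position_error", "gene(s) with start > end: %s",
               paste(head(positions$gene[positions$start > positions$end], 5),
                     collapse = ", "))
  if (any(positions$start < 1))
    stop_named("position_error", "coordinates must be 1-based positive")
  if (anyDuplicated(positions$gene))
    stop_named("position_error", "duplicate gene rows in position table")
  positions[order(chrom_rank(positions$chrom), positions$start), , drop = FALSE]
}

#' @rdname read_gene_positions
#' @export
write_gene_positions <- function(positions, path) {
  write.table(positions[c("gene", "chrom", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TISSUES <- c("LN", "PB")
STATUSES <- c("ND", "RR", "control")

#' Read per-cell metadata
#'
#' TSV with columns barcode, sample, patient, tissue (LN/PB), status
#' (ND/RR/control), cluster. Cluster labels are free strings consumed as
#' input; they are never computed here.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_cellmeta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "sample", "patient", "tissue", "status", "cluster")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_named("missing_column_error", "cell metadata lacks column(s): %s",
               paste(absent, collapse = ", "))
  if (anyDuplicated(df$barcode))
    stop_named("cellmeta_error", "duplicate barcodes in cell metadata")
  if (!all(df$tissue %in% TISSUES))
    stop_named("cellmeta_error", "tissue values must be one of: %s",
               paste(TISSUES, collapse = ", "))
  if (!all(df$status %in% STATUSES))
    stop_named("cellmeta_error", "status values must be one of: %s",
               paste(STATUSES, collapse = ", "))
  df
}

#' @rdname read_cellmeta
#' @param meta cell metadata table.
#' @export
write_cellmeta <- function(meta, path) {
  write.table(meta[c("barcode", "sample", "patient", "tissue", "status", "cluster")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segmented-cell spatial table (IMC dialect)
#'
#' CSV with columns image_id, x_um, y_um, cell_type; coordinates are
#' micrometres and must be non-negative.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_spatial <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_um", "y_um", "cell_type")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_named("missing_column_error", "spatial table lacks column(s): %s",
               paste(absent, collapse = ", "))
  if (any(df$x_um < 0) || any(df$y_um < 0))
    stop_named("spatial_error", "negative coordinates in spatial table")
  df
}

#' @rdname read_spatial
#' @param cells spatial cell table.
#' @export
write_spatial <- function(cells, path) {
  write.csv(cells[c("image_id", "x_um", "y_um", "cell_type")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
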