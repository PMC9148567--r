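#' Write / read a contact matrix as dense TSV
#'
#' Row and column identifiers (primer ids or bin start coordinates) go in
#' the first column / header line; NA cells are written as `NA`.
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @export
write_dense_matrix <- function(mat, path) {
  if (is.null(rownames(mat)))
    rownames(mat) <- seq_len(nrow(mat))
  if (is.null(colnames(mat)))
    colnames(mat) <- seq_len(ncol(mat))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_dense_matrix
#' @return `read_dense_matrix()` returns the matrix.
#' @export
read_dense_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a matrix as sparse triplet TSV (row_id, col_id, value)
#'
#' Zero and NA cells are omitted on write; missing cells read back as the
#' given fill.
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @export
write_sparse_triplets <- function(mat, path) {
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat))
  idx <- which(!is.na(mat) & mat != 0, arr.ind = TRUE)
  df <- data.frame(row_id = rownames(mat)[idx[, 1L]],
                   col_id = colnames(mat)[idx[, 2L]],
                   value = mat[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sparse_triplets
#' @param row_ids,col_ids Full dimension ids (ordering) of the dense
#'   matrix to reconstruct.
#' @param fill Value for absent cells (default 0).
#' @return `read_sparse_triplets()` returns the dense matrix.
#' @export
read_sparse_triplets <- function(path, row_ids, col_ids, fill = 0) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric"))
  mat <- matrix(fill, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
  mat[cbind(match(df$row_id, row_ids), match(df$col_id, col_ids))] <-
    df$value
  mat
}

#' Write / read a CTCF site table (position, orientation, strength TSV)
#'
#' @param sites A `ctcf_sites` table.
#' @param path File path.
#' @export
write_ctcf_table <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ctcf_table
#' @export
read_ctcf_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ctcf_sites(df$position, df$orientation, df$strength)
}

#' Write / read a rearrangement spec as a YAML config entry
#'
#' @param spec A `rearrangement_spec`.
#' @param path File path.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(list(kind = spec$kind, start = spec$start_bp,
                        end = spec$end_bp, build_tag = spec$build_tag),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  rearrangement_spec(x$kind, x$start, x$end,
                     if (is.null(x$build_tag)) "" else x$build_tag)
}

#' Write / read junction reads as FASTQ
#'
#' Quality is constant ("I", Phred 40) - synthetic reads carry no error
#' model. Writing is deterministic, so a fixed simulation seed yields a
#' byte-identical file.
#'
#' @param reads Named character vector of read sequences.
#' @param path File path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      vapply(nchar(reads), function(n)
        paste(rep("I", n), collapse = ""), character(1))))
  invisible(path)
}

#' @rdname write_fastq
#' @return `read_fastq()` returns a named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Export an insulation profile as bedGraph and boundaries as BED
#'
#' @param profile An `insulation_profile`.
#' @param path File path.
#' @param chrom Chromosome name.
#' @export
write_insulation_bedgraph <- function(profile, path, chrom = "chrSyn") {
  def <- profile[profile$defined, , drop = FALSE]
  res <- diff(profile$bin_start[1:2])
  df <- data.frame(chrom = chrom, start = def$bin_start,
                   end = def$bin_start + res, score = def$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_insulation_bedgraph
#' @param boundaries Data frame from [call_boundaries()].
#' @param resolution_bp Bin width for the BED intervals.
#' @export
write_boundaries_bed <- function(boundaries, path, resolution_bp = 6000,
                                 chrom = "chrSyn") {
  df <- data.frame(chrom = chrom, start = boundaries$bin_start,
                   end = boundaries$bin_start + resolution_bp,
                   name = sprintf("boundary_%d", seq_len(nrow(boundaries))),
                   score = round(1000 * pmin(boundaries$prominence, 1)),
                   strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
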