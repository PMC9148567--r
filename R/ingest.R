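#' Write / read a 5C primer table as BED6-style TSV
#'
#' Columns: chrom, start, end, primer_id, score (1 = efficient, 0 =
#' inefficient), strand (`+` forward / `-` reverse), and an optional
#' seventh sequence column. Coordinates are 0-based half-open (BED
#' convention). A write -> read round trip is the identity.
#'
#' @param primers `fivec_primers` table.
#' @param path Output file.
#' @param chrom Chromosome name for the first column.
#' @export
write_primer_table <- function(primers, path, chrom = "chrSyn") {
  bed <- data.frame(
    chrom = chrom,
    start = primers$start,
    end = primers$end,
    name = primers$primer_id,
    score = as.integer(primers$efficient),
    strand = ifelse(primers$category == "forward", "+", "-"),
    stringsAsFactors = FALSE)
  if (!is.null(primers$sequence)) bed$sequence <- primers$sequence
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_primer_table
#' @param require_alternating Passed to [validate_primers()].
#' @return `read_primer_table()` returns a validated `fivec_primers`
#'   table sorted by start.
#' @export
read_primer_table <- function(path, require_alternating = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no primers in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad))
    stop("malformed primer record at line ", bad[1L], " of ", path,
         " (expected >= 6 tab-separated fields)")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates at line ",
         which(is.na(start) | is.na(end))[1L], " of ", path)
  strand <- get(6)
  if (!all(strand %in% c("+", "-")))
    stop("invalid strand at line ", which(!strand %in% c("+", "-"))[1L],
         " of ", path)
  primers <- data.frame(
    primer_id = get(4),
    fragment = seq_along(lines),
    start = start,
    end = end,
    midpoint = (start + end) / 2,
    category = ifelse(strand == "+", "forward", "reverse"),
    sequence = if (any(nf >= 7L)) get(7) else NA_character_,
    efficient = get(5) != "0",
    stringsAsFactors = FALSE)
  primers <- primers[order(primers$start), , drop = FALSE]
  rownames(primers) <- NULL
  primers$fragment <- seq_len(nrow(primers))
  class(primers) <- c("fivec_primers", "data.frame")
  validate_primers(primers, require_alternating = require_alternating)
  primers
}

#' Count primer-pair contacts from ligation-junction reads
#'
#' A read exactly equal to the concatenation of a forward primer sequence
#' and a reverse primer sequence increments the corresponding cell of the
#' forward x reverse count matrix; any other read is discarded. Matched
#' plus discarded reads always equal the input read count.
#'
#' @param reads Character vector of read sequences (as from
#'   [simulate_junction_reads()]), or a path to a FASTQ file.
#' @param primers `fivec_primers` table with pairwise-distinct sequences.
#' @return A `raw_contact_map` with integer counts,
#'   `total_matched_reads` and `discarded_reads`.
#' @export
count_contacts <- function(reads, primers) {
  if (length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- toupper(as.character(reads))
  if (is.null(primers$sequence) || anyNA(primers$sequence))
    stop("all primers need sequences")
  if (anyDuplicated(primers$sequence))
    stop("duplicate primer sequences make the reference ambiguous")
  fwd <- primers[primers$category == "forward", , drop = FALSE]
  rev <- primers[primers$category == "reverse", , drop = FALSE]
  counts <- matrix(0L, nrow(fwd), ncol = nrow(rev),
                   dimnames = list(fwd$primer_id, rev$primer_id))
  flen <- nchar(fwd$sequence)
  matched <- 0L
  if (length(unique(flen)) == 1L) {
    lf <- flen[1L]
    fi <- match(substr(reads, 1L, lf), fwd$sequence)
    rj <- match(substr(reads, lf + 1L, nchar(reads)), rev$sequence)
    ok <- !is.na(fi) & !is.na(rj)
  } else {
    key <- as.vector(outer(fwd$sequence, rev$sequence, paste0))
    hit <- match(reads, key)
    fi <- (hit - 1L) %% nrow(fwd) + 1L
    rj <- (hit - 1L) %/% nrow(fwd) + 1L
    ok <- !is.na(hit)
  }
  if (any(ok)) {
    tab <- table(factor(fi[ok], seq_len(nrow(fwd))),
                 factor(rj[ok], seq_len(nrow(rev))))
    counts[] <- counts + as.integer(tab)
    matched <- sum(ok)
  }
  new_raw_contact_map(counts, fwd, rev,
                      total_matched = matched,
                      discarded = length(reads) - matched)
}

#' Discard inefficient primers from a contact map
#'
#' Either an explicit list of primer ids (mirroring a prior-knowledge list
#' of inefficient primers) or a percentile rule: primers whose total counts
#' fall below the given percentile of per-primer totals are masked. Masked
#' primers keep their counts but contribute to no downstream statistic.
#'
#' @param map A `raw_contact_map`.
#' @param flag_list Character vector of primer ids to mask.
#' @param min_total_percentile Percentile in `[0, 100)`; primers with
#'   totals below this percentile of all per-primer totals are masked.
#' @return The map with updated `fwd_mask` / `rev_mask`.
#' @export
discard_primers <- function(map, flag_list = NULL,
                            min_total_percentile = NULL) {
  stopifnot(inherits(map, "raw_contact_map"))
  if (!is.null(flag_list) && length(flag_list)) {
    unknown <- setdiff(flag_list,
                       c(map$fwd$primer_id, map$rev$primer_id))
    if (length(unknown))
      stop("unknown primer id: ", paste(unknown, collapse = ", "))
    map$fwd_mask[map$fwd$primer_id %in% flag_list] <- FALSE
    map$rev_mask[map$rev$primer_id %in% flag_list] <- FALSE
  }
  if (!is.null(min_total_percentile)) {
    if (min_total_percentile < 0 || min_total_percentile >= 100)
      stop("min_total_percentile must be in [0, 100)")
    totals <- c(rowSums(map$counts), colSums(map$counts))
    thr <- stats::quantile(totals, min_total_percentile / 100, names = FALSE)
    map$fwd_mask[rowSums(map$counts) < thr] <- FALSE
    map$rev_mask[colSums(map$counts) < thr] <- FALSE
  }
  map
}
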