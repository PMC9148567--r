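#' Generate a fragmented locus layout with an alternating 5C primer set
#'
#' Constructs an idealised restriction-fragmented locus (the synthetic
#' stand-in for a HindIII-digested ~1 Mb region) together with a
#' double-alternating 5C primer set: one primer per fragment, centred in the
#' fragment, with categories alternating forward/reverse along the
#' chromosome starting with forward. Fragments tile `[0, length_bp)` in
#' 0-based half-open coordinates. Fragment widths are uniform so that the
#' primer-midpoint grid is regular; this makes grid-aligned virtual
#' inversions exactly self-consistent (see the methods vignette).
#'
#' @param length_bp Locus length in bp (positive integer).
#' @param n_fragments Number of restriction fragments (>= 2).
#' @param primer_len Primer length in bp; must be smaller than the smallest
#'   fragment.
#' @param seed Integer seed driving primer sequence generation.
#' @param chrom Chromosome name used in exported tables.
#' @return A list with components `layout` (class `fivec_layout`: `chrom`,
#'   `length_bp`, `fragment_bounds` of length `n_fragments + 1`) and
#'   `primers` (class `fivec_primers`, a data.frame with columns
#'   `primer_id`, `fragment`, `start`, `end`, `midpoint`, `category`,
#'   `sequence`, `efficient`).
#' @examples
#' lp <- make_layout(300000, 50, 30, seed = 7)
#' table(lp$primers$category)
#' @export
make_layout <- function(length_bp, n_fragments, primer_len = 30L, seed = 1L,
                        chrom = "chrSyn") {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp <= 0)
    stop("'length_bp' must be a positive scalar")
  if (!is.numeric(n_fragments) || length(n_fragments) != 1L || n_fragments < 2)
    stop("'n_fragments' must be >= 2")
  length_bp <- as.integer(length_bp)
  n_fragments <- as.integer(n_fragments)
  bounds <- round(seq(0, length_bp, length.out = n_fragments + 1L))
  widths <- diff(bounds)
  if (any(widths <= primer_len))
    stop("'primer_len' must be smaller than the smallest fragment")

  start <- floor((bounds[-length(bounds)] + bounds[-1L]) / 2 - primer_len / 2)
  end <- start + primer_len
  category <- rep_len(c("forward", "reverse"), n_fragments)
  prefix <- ifelse(category == "forward", "F", "R")
  primer_id <- paste0(prefix, "_", seq_len(n_fragments))

  set.seed(as.integer(seed))
  sequence <- random_distinct_dna(n_fragments, primer_len)

  layout <- structure(
    list(chrom = chrom, length_bp = length_bp, fragment_bounds = bounds),
    class = "fivec_layout")
  primers <- data.frame(
    primer_id = primer_id,
    fragment = seq_len(n_fragments),
    start = as.integer(start),
    end = as.integer(end),
    midpoint = (start + end) / 2,
    category = category,
    sequence = sequence,
    efficient = TRUE,
    stringsAsFactors = FALSE)
  class(primers) <- c("fivec_primers", "data.frame")
  validate_primers(primers)
  list(layout = layout, primers = primers)
}

random_distinct_dna <- function(n, len, max_tries = 20L) {
  draw <- function(k) {
    vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  }
  seqs <- draw(n)
  tries <- 0L
  while (anyDuplicated(seqs) && tries < max_tries) {
    dup <- duplicated(seqs)
    seqs[dup] <- draw(sum(dup))
    tries <- tries + 1L
  }
  if (anyDuplicated(seqs)) stop("could not generate distinct primer sequences")
  seqs
}

#' Validate a 5C primer set
#'
#' Checks the double-alternating 5C design contract: primers sorted by
#' start, non-overlapping, categories alternating along the chromosome.
#'
#' @param primers A `fivec_primers` data.frame.
#' @param require_alternating Enforce strict forward/reverse alternation
#'   (TRUE for as-designed primer sets; rearranged sets may relax it).
#' @return Invisibly, `primers`; errors describe the first offending row.
#' @export
validate_primers <- function(primers, require_alternating = TRUE) {
  need <- c("primer_id", "start", "end", "category")
  miss <- setdiff(need, names(primers))
  if (length(miss))
    stop("primer table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(primers) == 0L) stop("no primers")
  if (is.unsorted(primers$start, strictly = TRUE))
    stop("primers must be sorted by start with no duplicates")
  if (any(primers$end <= primers$start))
    stop("primer end must exceed start (row ",
         which(primers$end <= primers$start)[1L], ")")
  ov <- which(primers$start[-1L] < primers$end[-nrow(primers)])
  if (length(ov))
    stop("overlapping primers at rows ", ov[1L], " and ", ov[1L] + 1L)
  if (!all(primers$category %in% c("forward", "reverse")))
    stop("primer category must be 'forward' or 'reverse'")
  if (require_alternating && nrow(primers) > 1L) {
    same <- which(primers$category[-1L] == primers$category[-nrow(primers)])
    if (length(same))
      stop("primer categories do not alternate at row ", same[1L] + 1L)
  }
  invisible(primers)
}

#' CTCF site table
#'
#' @param position_bp Motif positions (0-based bp).
#' @param orientation `"right"` (motif points toward increasing coordinate)
#'   or `"left"`.
#' @param strength Non-negative loop-anchor strengths.
#' @param length_bp Optional locus length for bounds checking.
#' @return A data.frame of class `ctcf_sites`, sorted by position.
#' @export
ctcf_sites <- function(position_bp, orientation, strength = 1,
                       length_bp = NULL) {
  if (length(position_bp) == 0L) {
    x <- data.frame(position = numeric(0), orientation = character(0),
                    strength = numeric(0), stringsAsFactors = FALSE)
    class(x) <- c("ctcf_sites", "data.frame")
    return(x)
  }
  orientation <- rep_len(orientation, length(position_bp))
  strength <- rep_len(strength, length(position_bp))
  if (!all(orientation %in% c("right", "left")))
    stop("orientation must be 'right' or 'left'")
  if (any(strength < 0)) stop("strength must be >= 0")
  if (any(position_bp < 0)) stop("position must be >= 0")
  if (!is.null(length_bp) && any(position_bp >= length_bp))
    stop("CTCF site position outside the locus")
  o <- order(position_bp)
  x <- data.frame(position = position_bp[o], orientation = orientation[o],
                  strength = strength[o], stringsAsFactors = FALSE)
  class(x) <- c("ctcf_sites", "data.frame")
  x
}

#' Structural rearrangement specification
#'
#' A 0-based half-open segment `[start_bp, end_bp)` to be inverted or
#' deleted, as determined from sequenced breakpoints.
#'
#' @param kind `"inversion"` or `"deletion"`.
#' @param start_bp,end_bp Breakpoints, `start_bp < end_bp`.
#' @param build_tag Free-text label (e.g. genome build or clone).
#' @return A list of class `rearrangement_spec` with a `length_bp` field.
#' @examples
#' # the study's large inversion, from its printed clone-1 breakpoints
#' inv <- rearrangement_spec("inversion", 100377328, 100622017, "mm9-clone1")
#' inv$length_bp  # 244689 bp, ~245 kb
#' @export
rearrangement_spec <- function(kind = c("inversion", "deletion"),
                               start_bp, end_bp, build_tag = "") {
  kind <- match.arg(kind)
  if (!is.numeric(start_bp) || !is.numeric(end_bp) || start_bp >= end_bp)
    stop("need start_bp < end_bp")
  if (start_bp < 0) stop("start_bp must be >= 0")
  structure(
    list(kind = kind, start_bp = as.numeric(start_bp),
         end_bp = as.numeric(end_bp),
         length_bp = as.numeric(end_bp - start_bp), build_tag = build_tag),
    class = "rearrangement_spec")
}

#' @export
print.rearrangement_spec <- function(x, ...) {
  cat(sprintf("<%s> [%s, %s) length %s bp %s\n", x$kind,
              format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              format(x$length_bp, big.mark = ","),
              if (nzchar(x$build_tag)) paste0("(", x$build_tag, ")") else ""))
  invisible(x)
}

check_spec_within <- function(spec, length_bp) {
  if (spec$start_bp < 0 || spec$end_bp > length_bp)
    stop("rearrangement segment lies outside the genome [0, ", length_bp, ")")
}

#' Map point coordinates through a rearrangement
#'
#' Inversion `[a, b)`: a base at `p` in the segment maps to `a + b - 1 - p`;
#' positions outside are unchanged. Deletion `[a, b)`: positions inside map
#' to `NA` (removed); positions at or beyond `b` shift by `-(b - a)`.
#'
#' @param positions Numeric vector of 0-based point coordinates.
#' @param spec A `rearrangement_spec`.
#' @return Numeric vector of mapped coordinates (NA = removed).
#' @export
map_coordinates <- function(positions, spec) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  a <- spec$start_bp; b <- spec$end_bp
  out <- positions
  inside <- positions >= a & positions < b
  if (spec$kind == "inversion") {
    out[inside] <- a + b - 1 - positions[inside]
  } else {
    out[inside] <- NA_real_
    shift <- positions >= b
    out[shift] <- positions[shift] - (b - a)
  }
  out
}

# Interval mapping: [s, e) inside an inverted [a, b) becomes [a+b-e, a+b-s);
# intervals straddling a breakpoint are invalidated (NA).
map_intervals <- function(start, end, spec) {
  a <- spec$start_bp; b <- spec$end_bp
  inside <- start >= a & end <= b
  outside <- end <= a | start >= b
  straddle <- !inside & !outside
  ns <- start; ne <- end
  if (spec$kind == "inversion") {
    ns[inside] <- a + b - end[inside]
    ne[inside] <- a + b - start[inside]
  } else {
    ns[inside] <- NA_real_; ne[inside] <- NA_real_
    shift <- start >= b
    ns[shift] <- start[shift] - (b - a)
    ne[shift] <- end[shift] - (b - a)
  }
  ns[straddle] <- NA_real_; ne[straddle] <- NA_real_
  data.frame(start = ns, end = ne)
}

#' Apply a structural rearrangement to a layout and its CTCF sites
#'
#' Produces the mutant-allele genome: for an inversion, fragment boundaries
#' and CTCF sites inside the segment are reflected (`p -> a + b - 1 - p` for
#' point features) and CTCF orientations flip; the breakpoints become
#' fragment boundaries if they were not already. For a deletion, features
#' inside the segment are removed, downstream coordinates shift left by the
#' deleted length and the genome shrinks accordingly. Applying the same
#' inversion twice restores the input.
#'
#' @param layout A `fivec_layout`.
#' @param sites A `ctcf_sites` table (may be empty).
#' @param spec A `rearrangement_spec` inside the genome.
#' @return A list with mutated `layout` and `sites`.
#' @export
apply_rearrangement <- function(layout, sites, spec) {
  stopifnot(inherits(layout, "fivec_layout"),
            inherits(spec, "rearrangement_spec"))
  check_spec_within(spec, layout$length_bp)
  a <- spec$start_bp; b <- spec$end_bp
  bounds <- layout$fragment_bounds

  if (spec$kind == "inversion") {
    inner <- bounds[bounds > a & bounds < b]
    keep <- bounds[bounds <= a | bounds >= b]
    new_bounds <- sort(unique(c(keep, a + b - inner, a, b)))
    new_len <- layout$length_bp
  } else {
    keep_lo <- bounds[bounds <= a]
    keep_hi <- bounds[bounds >= b] - (b - a)
    new_bounds <- sort(unique(c(keep_lo, a, keep_hi)))
    new_len <- layout$length_bp - (b - a)
  }
  new_layout <- structure(
    list(chrom = layout$chrom, length_bp = new_len,
         fragment_bounds = new_bounds),
    class = "fivec_layout")

  if (is.null(sites) || nrow(sites) == 0L) {
    new_sites <- ctcf_sites(numeric(0), character(0))
  } else {
    pos <- map_coordinates(sites$position, spec)
    ori <- sites$orientation
    if (spec$kind == "inversion") {
      inside <- sites$position >= a & sites$position < b
      ori[inside] <- ifelse(ori[inside] == "right", "left", "right")
    }
    keep <- !is.na(pos)
    new_sites <- ctcf_sites(pos[keep], ori[keep], sites$strength[keep])
  }
  list(layout = new_layout, sites = new_sites)
}

#' Express a primer set in mutant-allele coordinates
#'
#' Maps each primer interval through the rearrangement while keeping the
#' original (reference) row order and primer identities, so that a contact
#' map simulated on the mutant allele stays indexed by reference primer.
#' Inverted primers flip category (a forward primer reads off the reverse
#' strand after inversion); primers straddling a breakpoint or inside a
#' deletion are dropped (their ligation junctions are chimeric).
#'
#' @param primers A `fivec_primers` table in reference coordinates.
#' @param spec A `rearrangement_spec`.
#' @return The primer table with mutant `start`, `end`, `midpoint` and
#'   `category`, plus a `ref_index` column giving each row's index in the
#'   input table. Row order is the reference order.
#' @export
rearrange_primers <- function(primers, spec) {
  iv <- map_intervals(primers$start, primers$end, spec)
  out <- primers
  out$ref_index <- seq_len(nrow(primers))
  out$start <- iv$start
  out$end <- iv$end
  out$midpoint <- (iv$start + iv$end) / 2
  if (spec$kind == "inversion") {
    inside <- !is.na(iv$start) &
      primers$start >= spec$start_bp & primers$end <= spec$end_bp
    out$category[inside] <- ifelse(out$category[inside] == "forward",
                                   "reverse", "forward")
  }
  out <- out[!is.na(out$start), , drop = FALSE]
  class(out) <- c("fivec_primers", "data.frame")
  out
}
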