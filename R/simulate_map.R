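#' Simulation parameters for synthetic 5C contact maps
#'
#' The generative model for the expected contact matrix between forward
#' primer `i` and reverse primer `j` at genomic separation `d_ij` is
#' \deqn{\Lambda_{ij} = depth \cdot c \cdot d_{ij}^{-\alpha} \cdot
#'   T_{ij} \cdot L_{ij}}
#' where `T_ij` is `tad_factor` if both primer midpoints fall in the same
#' TAD and `cross_boundary_factor` otherwise, `L_ij = 1 +
#' loop_strength * s_a * s_b` if the pixel is the nearest primer pair to a
#' convergent CTCF site pair (upstream motif oriented right, downstream
#' motif oriented left) with strengths `s_a`, `s_b`, and `c` normalises
#' the matrix total to `depth`. Counts are independent Poisson draws.
#'
#' @param decay_exponent Power-law distance-decay exponent, > 0.
#' @param depth Expected total count over the map, > 0.
#' @param tad_factor Within-TAD contact enrichment, >= 1.
#' @param cross_boundary_factor Cross-TAD attenuation in (0, 1].
#' @param loop_strength Convergent-loop enrichment coefficient, >= 0.
#' @param seed Integer seed for the Poisson draw.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(decay_exponent = 1, depth = 1e6, tad_factor = 2,
                       cross_boundary_factor = 0.5, loop_strength = 3,
                       seed = 1L) {
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (depth <= 0) stop("depth must be > 0")
  if (tad_factor < 1) stop("tad_factor must be >= 1")
  if (cross_boundary_factor <= 0 || cross_boundary_factor > 1)
    stop("cross_boundary_factor must be in (0, 1]")
  if (loop_strength < 0) stop("loop_strength must be >= 0")
  structure(list(decay_exponent = decay_exponent, depth = depth,
                 tad_factor = tad_factor,
                 cross_boundary_factor = cross_boundary_factor,
                 loop_strength = loop_strength, seed = as.integer(seed)),
            class = "sim_params")
}

new_raw_contact_map <- function(counts, fwd, rev, values = NULL,
                                total_matched = sum(counts),
                                discarded = 0L) {
  structure(list(
    counts = counts,
    values = values,                # normalised values, NULL until scaled
    fwd = fwd, rev = rev,
    fwd_mask = rep(TRUE, nrow(fwd)),    # TRUE = primer kept
    rev_mask = rep(TRUE, nrow(rev)),
    pixel_mask = matrix(FALSE, nrow(counts), ncol(counts)),
    total_matched_reads = total_matched,
    discarded_reads = discarded,
    normalized = !is.null(values)),
    class = "raw_contact_map")
}

#' @export
print.raw_contact_map <- function(x, ...) {
  cat(sprintf(
    "<raw_contact_map> %d forward x %d reverse primers, %s reads (%s discarded)%s\n",
    nrow(x$counts), ncol(x$counts),
    format(x$total_matched_reads, big.mark = ","),
    format(x$discarded_reads, big.mark = ","),
    if (isTRUE(x$normalized)) ", normalised" else ""))
  invisible(x)
}

# TAD id of a midpoint given internal boundary positions
tad_id <- function(mid, boundaries) {
  if (length(boundaries) == 0L) rep(1L, length(mid))
  else findInterval(mid, sort(boundaries)) + 1L
}

#' Simulate a 5C contact map with programmed TADs and CTCF loops
#'
#' Builds the expected forward x reverse contact matrix under the model of
#' [sim_params()] and draws Poisson counts from it. The matrix rows/columns
#' follow the order of the forward/reverse primers in `primers`, so a map
#' simulated on a rearranged primer set (see [rearrange_primers()]) stays
#' indexed by reference primer identity.
#'
#' Loops are placed on the single primer pair nearest to each convergent
#' CTCF site pair; when several convergent pairs select the same pixel the
#' strongest enrichment wins (no stacking). A convergent pair whose two
#' nearest primers share a category has no forward x reverse pixel and is
#' skipped.
#'
#' @param primers `fivec_primers` table (mutant coordinates allowed).
#' @param sites Optional `ctcf_sites` table.
#' @param tad_boundaries Internal TAD boundary positions in bp.
#' @param params A `sim_params` object.
#' @return A list with `lambda` (expected matrix), `map` (a
#'   `raw_contact_map` holding the Poisson counts) and the loop pixel
#'   bookkeeping in `loops` (data.frame of fwd/rev indices and factors).
#' @export
simulate_contact_map <- function(primers, sites = NULL,
                                 tad_boundaries = numeric(0),
                                 params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  fwd <- primers[primers$category == "forward", , drop = FALSE]
  rev <- primers[primers$category == "reverse", , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L)
    stop("need at least one forward and one reverse primer")

  d <- abs(outer(fwd$midpoint, rev$midpoint, "-"))
  d[d < 1] <- 1
  lambda <- d^(-params$decay_exponent)

  tf <- tad_id(fwd$midpoint, tad_boundaries)
  tr <- tad_id(rev$midpoint, tad_boundaries)
  same <- outer(tf, tr, "==")
  lambda <- lambda * ifelse(same, params$tad_factor,
                            params$cross_boundary_factor)

  loops <- data.frame(fwd = integer(0), rev = integer(0), factor = numeric(0))
  if (!is.null(sites) && nrow(sites) >= 2L && params$loop_strength > 0) {
    mids <- primers$midpoint
    nearest <- function(p) which.min(abs(mids - p))
    n <- nrow(sites)
    for (i in seq_len(n - 1L)) {
      if (sites$orientation[i] != "right") next
      for (j in seq((i + 1L), n)) {
        if (sites$orientation[j] != "left") next
        pa <- nearest(sites$position[i])
        pb <- nearest(sites$position[j])
        ca <- primers$category[pa]; cb <- primers$category[pb]
        if (ca == cb) next
        if (ca == "forward") {
          fi <- match(primers$primer_id[pa], fwd$primer_id)
          rj <- match(primers$primer_id[pb], rev$primer_id)
        } else {
          fi <- match(primers$primer_id[pb], fwd$primer_id)
          rj <- match(primers$primer_id[pa], rev$primer_id)
        }
        fac <- 1 + params$loop_strength * sites$strength[i] * sites$strength[j]
        prev <- loops$factor[loops$fwd == fi & loops$rev == rj]
        if (length(prev) == 0L) {
          loops <- rbind(loops,
                         data.frame(fwd = fi, rev = rj, factor = fac))
        } else if (fac > prev) {
          loops$factor[loops$fwd == fi & loops$rev == rj] <- fac
        }
      }
    }
    if (nrow(loops))
      lambda[cbind(loops$fwd, loops$rev)] <-
        lambda[cbind(loops$fwd, loops$rev)] * loops$factor
  }

  lambda <- lambda * params$depth / sum(lambda)
  dimnames(lambda) <- list(fwd$primer_id, rev$primer_id)

  set.seed(params$seed)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda),
                   dimnames = dimnames(lambda))
  list(lambda = lambda,
       map = new_raw_contact_map(counts, fwd, rev),
       loops = loops)
}

#' Simulate 5C ligation-junction reads from a contact map
#'
#' Each read is the concatenation of a forward primer sequence and a
#' reverse primer sequence, for a primer pair drawn with probability
#' proportional to its count in `map`. The read id records the true pair,
#' so recovered counts can be compared against ground truth.
#'
#' @param map A `raw_contact_map` whose primers carry sequences.
#' @param n_reads Number of reads to draw (> 0).
#' @param seed Integer seed.
#' @return A named character vector of read sequences; names are
#'   `read_<k>|<fwd_id>|<rev_id>`. Write with [write_fastq()].
#' @export
simulate_junction_reads <- function(map, n_reads, seed = 1L) {
  stopifnot(inherits(map, "raw_contact_map"))
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (is.null(map$fwd$sequence) || is.null(map$rev$sequence) ||
      anyNA(map$fwd$sequence) || anyNA(map$rev$sequence))
    stop("primer sequences are required to simulate reads")
  k <- map$counts
  if (sum(k) <= 0) stop("contact map has no counts to sample from")
  set.seed(as.integer(seed))
  idx <- sample.int(length(k), n_reads, replace = TRUE, prob = as.vector(k))
  fi <- (idx - 1L) %% nrow(k) + 1L
  rj <- (idx - 1L) %/% nrow(k) + 1L
  reads <- paste0(map$fwd$sequence[fi], map$rev$sequence[rj])
  names(reads) <- sprintf("read_%d|%s|%s", seq_len(n_reads),
                          map$fwd$primer_id[fi], map$rev$primer_id[rj])
  reads
}

#' A ready-made synthetic X-inactivation-centre locus
#'
#' A ~1 Mb locus partitioned into a ~300 kb TAD (the Tsix-TAD analogue),
#' a neighbouring 300 kb TAD (the Xist-TAD analogue) and downstream TADs,
#' with three intra-TAD CTCF anchor clusters arranged like Linx (right-
#' oriented, strongest), Chic1 (left-oriented) and Xite (left-oriented at
#' the TAD boundary). Ships grid-aligned analogues of the study's
#' rearrangements: a 240 kb intra-TAD inversion covering the Linx and Chic1
#' anchors but not Xite, and a 14,106 bp deletion removing the Chic1
#' anchor.
#'
#' @param seed Seed passed to [make_layout()] (primer sequences).
#' @return A list with `layout`, `primers`, `sites`, `tad_boundaries`,
#'   `inversion` and `deletion` (rearrangement specs) and `anchors`
#'   (named anchor positions).
#' @export
xic_locus <- function(seed = 1L) {
  lp <- make_layout(996000, 166, 30, seed = seed, chrom = "chrXsyn")
  anchors <- c(Linx = 78000, Chic1 = 180000, Xite = 288000)
  sites <- ctcf_sites(position_bp = unname(anchors),
                      orientation = c("right", "left", "left"),
                      strength = c(1.5, 1, 1),
                      length_bp = lp$layout$length_bp)
  list(layout = lp$layout,
       primers = lp$primers,
       sites = sites,
       tad_boundaries = c(300000, 600000, 804000),
       inversion = rearrangement_spec("inversion", 30000, 270000,
                                      "synthetic Tsix-TAD inversion"),
       deletion = rearrangement_spec("deletion", 177000, 191106,
                                     "synthetic Chic1 CTCF-cluster deletion"),
       anchors = anchors)
}
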