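#' Build the coordinate permutation induced by a virtual inversion
#'
#' For an inversion `[a, b)`, elements (bins or primers) lying entirely
#' inside the segment are order-reversed: the element with midpoint `p` is
#' sent to the slot whose midpoint is nearest to the reflected position
#' (ties broken toward the lower index). Elements outside the segment map
#' to themselves; elements straddling a breakpoint are invalidated - the
#' true mutant junction is chimeric, and the corresponding rows/columns
#' are masked like the study's grey filtered pixels.
#'
#' @param starts,ends Element interval bounds (0-based half-open); for a
#'   `binned_map` pass [bin_intervals()].
#' @param spec A `rearrangement_spec` with `kind == "inversion"` inside
#'   the element span.
#' @return A `coordinate_permutation`: `index_map` (integer vector, NA =
#'   invalid), `invalid_indices`, `spec`. Restricted to valid indices the
#'   map is an involution.
#' @export
build_permutation <- function(starts, ends, spec) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  if (spec$kind != "inversion")
    stop("build_permutation handles inversions; see deletion_adjust()")
  a <- spec$start_bp; b <- spec$end_bp
  if (a < min(starts) || b > max(ends))
    stop("inversion segment outside the element span")
  n <- length(starts)
  mid <- (starts + ends) / 2
  inside <- starts >= a & ends <= b
  outside <- ends <= a | starts >= b
  straddle <- !inside & !outside
  index_map <- seq_len(n)
  index_map[straddle] <- NA_integer_
  if (any(inside)) {
    target_mid <- a + b - mid[inside]
    slots <- which(inside)
    assigned <- vapply(target_mid, function(p) {
      dd <- abs(mid[slots] - p)
      slots[which(dd == min(dd))[1L]]
    }, integer(1))
    index_map[inside] <- assigned
  }
  structure(list(index_map = index_map,
                 invalid_indices = which(straddle),
                 spec = spec),
            class = "coordinate_permutation")
}

#' Bin intervals of a binned map
#'
#' @param binned A `binned_map`.
#' @return A data.frame of bin `start` / `end` (half-open, one resolution
#'   step wide).
#' @export
bin_intervals <- function(binned) {
  data.frame(start = binned$bin_starts,
             end = binned$bin_starts + binned$resolution_bp)
}

#' Remap a matrix through a coordinate permutation
#'
#' `out[pi(i), pi(j)] = in[i, j]` for valid `i, j`; rows/columns of
#' invalid indices are NA. The multiset of valid values is conserved and
#' applying the same inversion permutation twice restores the input.
#'
#' @param mat A square matrix indexed like the permutation.
#' @param perm A `coordinate_permutation`.
#' @return The remapped matrix.
#' @export
remap_matrix <- function(mat, perm) {
  stopifnot(inherits(perm, "coordinate_permutation"))
  pi_ <- perm$index_map
  if (nrow(mat) != length(pi_) || ncol(mat) != length(pi_))
    stop("matrix dimensions do not match the permutation")
  out <- matrix(NA, nrow(mat), ncol(mat))
  mode(out) <- mode(mat)
  v <- which(!is.na(pi_))
  out[pi_[v], pi_[v]] <- mat[v, v]
  out
}

#' Remap a binned map onto the virtually inverted reference
#'
#' Applies [remap_matrix()] to the values, validity and pair-support
#' matrices of a `binned_map`, masking bins that straddle a breakpoint.
#'
#' @param binned A `binned_map` (the mutant-allele map indexed by
#'   reference bins).
#' @param perm A `coordinate_permutation` built on the same bin grid.
#' @return The remapped `binned_map`.
#' @export
remap_binned <- function(binned, perm) {
  stopifnot(inherits(binned, "binned_map"))
  out <- binned
  out$values <- remap_matrix(binned$values, perm)
  valid <- remap_matrix(binned$valid, perm)
  valid[is.na(valid)] <- FALSE
  out$valid <- valid
  np <- remap_matrix(binned$n_pairs, perm)
  np[is.na(np)] <- 0L
  out$n_pairs <- np
  out$values[!out$valid] <- NA_real_
  out
}

#' Deletion-aware distance adjustment
#'
#' For a deletion `[a, b)`, the genomic separation of an element pair that
#' spans the deletion shrinks by the deleted length on the mutant allele;
#' pairs on the same side are unchanged, and elements whose midpoint lies
#' inside the deletion are removed. Feeding the adjusted distances into
#' [distance_zscore()] assigns spanning pairs to their post-deletion
#' distance strata.
#'
#' @param binned A `binned_map` (or anything with `bin_starts` and
#'   `resolution_bp`).
#' @param spec A `rearrangement_spec` with `kind == "deletion"` inside
#'   the bin span.
#' @return A `distance_adjustment`: `distances` (bin x bin matrix in bp,
#'   NA for removed bins), `removed_indices`, `spanning` (logical
#'   matrix), `spec`.
#' @export
deletion_adjust <- function(binned, spec) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  if (spec$kind != "deletion")
    stop("deletion_adjust handles deletions; see build_permutation()")
  mids <- binned$bin_starts + binned$resolution_bp / 2
  if (spec$start_bp < 0 ||
      spec$end_bp > max(binned$bin_starts) + binned$resolution_bp)
    stop("deletion segment outside the bin span")
  a <- spec$start_bp; b <- spec$end_bp
  removed <- which(mids >= a & mids < b)
  d <- abs(outer(mids, mids, "-"))
  lo <- outer(mids, mids, pmin); hi <- outer(mids, mids, pmax)
  spanning <- lo < a & hi >= b
  d[spanning] <- d[spanning] - (b - a)
  if (length(removed)) {
    d[removed, ] <- NA_real_
    d[, removed] <- NA_real_
  }
  stopifnot(all(d >= 0, na.rm = TRUE))
  structure(list(distances = d, removed_indices = removed,
                 spanning = spanning, spec = spec),
            class = "distance_adjustment")
}
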