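#' Differential z-score map between two genotypes
#'
#' Pixel-wise subtraction of the z-score maps computed for each map
#' separately; pixels invalid or CV-masked in either input are masked in
#' the output (the study renders them grey). Antisymmetric in its
#' arguments.
#'
#' @param z_a,z_b `zscore_map`s on the same bin grid.
#' @return A `differential_map`: `delta` (z_a - z_b, NA off-mask) and
#'   `masked`.
#' @export
differential_map <- function(z_a, z_b) {
  stopifnot(inherits(z_a, "zscore_map"), inherits(z_b, "zscore_map"))
  if (!all(dim(z_a$z) == dim(z_b$z)))
    stop("z-score maps are on different bin grids")
  masked <- !z_a$valid | !z_b$valid
  delta <- z_a$z - z_b$z
  delta[masked] <- NA_real_
  structure(list(delta = delta, masked = masked),
            class = "differential_map")
}

#' Insulation-score profile of a binned map
#'
#' Crane-style sliding off-diagonal square: for bin `b` the raw score is
#' the mean of valid contacts in the square spanning the `square_bins`
#' bins upstream against the `square_bins` bins downstream of `b` - the
#' contacts that cross `b`. Scores are reported as log2 of the ratio to
#' the global mean of the raw scores, so the profile is invariant to
#' global rescaling of the map. Lower scores mean stronger insulation;
#' troughs mark TAD boundaries. Bins within `square_bins` of the map edge
#' or whose square holds fewer than `min_valid_frac` valid pixels are
#' undefined.
#'
#' @param binned A `binned_map` with at least `2 * square_bins + 1` bins.
#' @param square_bins Square side in bins (default 5, i.e. 30 kb at 6 kb
#'   resolution).
#' @param min_valid_frac Minimum fraction of valid pixels per square.
#' @return An `insulation_profile` data.frame: `bin`, `bin_start`,
#'   `raw`, `score`, `defined`.
#' @export
insulation_profile <- function(binned, square_bins = 5,
                               min_valid_frac = 0.25) {
  stopifnot(inherits(binned, "binned_map"))
  nb <- nrow(binned$values)
  if (nb < 2 * square_bins + 1)
    stop("map too small for the insulation square")
  raw <- rep(NA_real_, nb)
  for (b in seq(square_bins + 1L, nb - square_bins)) {
    rows <- (b - square_bins):(b - 1L)
    cols <- (b + 1L):(b + square_bins)
    vals <- binned$values[rows, cols]
    ok <- !is.na(vals)
    if (sum(ok) >= min_valid_frac * square_bins^2)
      raw[b] <- mean(vals[ok])
  }
  m <- mean(raw, na.rm = TRUE)
  score <- if (is.finite(m) && m > 0) log2(raw / m) else raw * NA_real_
  out <- data.frame(bin = seq_len(nb), bin_start = binned$bin_starts,
                    raw = raw, score = score, defined = !is.na(score))
  attr(out, "square_bins") <- square_bins
  class(out) <- c("insulation_profile", "data.frame")
  out
}

#' Call TAD boundaries as insulation troughs
#'
#' Boundaries are local minima of the insulation profile lying below both
#' flanking local maxima by at least `prominence` (log2 units). Plateau
#' minima resolve to their lowest-index bin; profile endpoints count as
#' flanking maxima.
#'
#' @param profile An `insulation_profile`.
#' @param prominence Minimum depth below both flanking maxima.
#' @return A data.frame of called boundaries: `bin`, `bin_start`,
#'   `score`, `prominence`.
#' @export
call_boundaries <- function(profile, prominence = 0.2) {
  stopifnot(inherits(profile, "insulation_profile"))
  def <- which(profile$defined)
  if (length(def) < 3L)
    stop("profile defined on fewer than 3 bins")
  s <- profile$score[def]
  n <- length(s)
  res <- data.frame(bin = integer(0), bin_start = numeric(0),
                    score = numeric(0), prominence = numeric(0))
  i <- 2L
  while (i <= n - 1L) {
    # plateau-aware local minimum: strictly below the previous distinct
    # value and at or below the next distinct one
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    if (s[i] < s[i - 1L] && j < n && s[i] < s[j + 1L]) {
      left_max <- local_flank_max(s, i, -1L)
      right_max <- local_flank_max(s, j, +1L)
      prom <- min(left_max, right_max) - s[i]
      if (prom >= prominence) {
        res <- rbind(res, data.frame(
          bin = profile$bin[def[i]],
          bin_start = profile$bin_start[def[i]],
          score = s[i], prominence = prom))
      }
    }
    i <- j + 1L
  }
  res
}

# highest value reached before the profile next turns down (walking away
# from a trough at index i in direction dir); endpoints act as maxima
local_flank_max <- function(s, i, dir) {
  n <- length(s)
  best <- s[i]
  j <- i + dir
  while (j >= 1L && j <= n) {
    if (s[j] > best) best <- s[j]
    else if (s[j] < best - 1e-15 && best > s[i]) break
    j <- j + dir
  }
  best
}
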