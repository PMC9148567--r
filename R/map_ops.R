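#' Pool replicate contact maps and normalise to counts per million
#'
#' Biological replicates are pooled by summing counts, then the pooled map
#' is scaled so that the total over unmasked cells is exactly 1e6
#' (counts-per-million). Masked primers are excluded from both the total
#' and the output values.
#'
#' @param maps A single `raw_contact_map` or a list of maps sharing primer
#'   sets and masks.
#' @return A `raw_contact_map` with a `values` matrix (NA on masked
#'   rows/columns) and `normalized = TRUE`.
#' @export
pool_and_normalize <- function(maps) {
  if (inherits(maps, "raw_contact_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (!identical(m$fwd$primer_id, ref$fwd$primer_id) ||
        !identical(m$rev$primer_id, ref$rev$primer_id))
      stop("maps to pool must share the same primer sets")
    if (!identical(m$fwd_mask, ref$fwd_mask) ||
        !identical(m$rev_mask, ref$rev_mask))
      stop("maps to pool must share the same primer masks")
  }
  counts <- Reduce(`+`, lapply(maps, `[[`, "counts"))
  vals <- counts * 1.0
  vals[!ref$fwd_mask, ] <- NA_real_
  vals[, !ref$rev_mask] <- NA_real_
  vals[ref$pixel_mask] <- NA_real_
  tot <- sum(vals, na.rm = TRUE)
  if (tot <= 0) stop("degenerate input: map has no counts on unmasked cells")
  out <- ref
  out$counts <- counts
  out$values <- vals * 1e6 / tot
  out$total_matched_reads <- sum(vapply(maps, `[[`, numeric(1),
                                        "total_matched_reads"))
  out$discarded_reads <- sum(vapply(maps, `[[`, numeric(1),
                                    "discarded_reads"))
  out$normalized <- TRUE
  out
}

# MAD-based robust sd on the log1p scale
log_mad_sd <- function(x) stats::mad(log1p(x))

#' Filter outlier probes and singleton pixels
#'
#' Probe outliers are primers whose total (over unmasked cells) exceeds
#' the median by more than `probe_mads` MAD-standard-deviations on the
#' log1p scale; they are masked like inefficient primers. Singletons are
#' isolated bright pixels: above the global `singleton_quantile` of
#' unmasked values and more than `singleton_ratio` times the maximum of
#' their 8 neighbours; they are masked individually. The thresholds are
#' explicit configurables - the filter is standard for 5C maps but its
#' constants are implementation choices.
#'
#' @param map A normalised `raw_contact_map`.
#' @param probe_mads Probe outlier threshold in MAD-sd units (default 3).
#' @param singleton_quantile Global quantile a singleton must exceed.
#' @param singleton_ratio Neighbour ratio a singleton must exceed.
#' @return The map with updated primer masks and `pixel_mask`; values on
#'   newly masked cells become NA and the map is rescaled to keep the
#'   unmasked total at 1e6.
#' @export
filter_outliers_singletons <- function(map, probe_mads = 3,
                                       singleton_quantile = 0.999,
                                       singleton_ratio = 10) {
  stopifnot(inherits(map, "raw_contact_map"))
  if (!isTRUE(map$normalized)) stop("normalise the map first")
  v <- map$values

  row_tot <- rowSums(v, na.rm = TRUE)
  col_tot <- colSums(v, na.rm = TRUE)
  totals <- c(row_tot[map$fwd_mask], col_tot[map$rev_mask])
  lt <- log1p(totals)
  thr <- stats::median(lt) + probe_mads * stats::mad(lt)
  map$fwd_mask[map$fwd_mask & log1p(row_tot) > thr &
                 stats::mad(lt) > 0] <- FALSE
  map$rev_mask[map$rev_mask & log1p(col_tot) > thr &
                 stats::mad(lt) > 0] <- FALSE
  v[!map$fwd_mask, ] <- NA_real_
  v[, !map$rev_mask] <- NA_real_

  ok <- !is.na(v)
  if (any(ok)) {
    q <- stats::quantile(v[ok], singleton_quantile, names = FALSE)
    nb_max <- neighbour_max(v)
    single <- ok & v > q & !is.na(nb_max) & v > singleton_ratio * nb_max
    map$pixel_mask[single] <- TRUE
    v[single] <- NA_real_
  }
  tot <- sum(v, na.rm = TRUE)
  if (tot <= 0) stop("degenerate input: nothing left after filtering")
  map$values <- v * 1e6 / tot
  map
}

# max over the 8 neighbours of each cell (NA-aware; all-NA -> NA)
neighbour_max <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(-Inf, nr, nc)
  any_nb <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src_r <- seq_len(nr) - di; src_c <- seq_len(nc) - dj
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    sub <- v[src_r[ok_r], src_c[ok_c], drop = FALSE]
    tgt <- out[ok_r, ok_c, drop = FALSE]
    has <- !is.na(sub)
    tgt[has] <- pmax(tgt[has], sub[has])
    out[ok_r, ok_c] <- tgt
    a <- any_nb[ok_r, ok_c, drop = FALSE]
    a[has] <- TRUE
    any_nb[ok_r, ok_c] <- a
  }
  out[!any_nb] <- NA_real_
  out
}

#' Bin a primer-level map with a running median
#'
#' Grid anchors are placed every `resolution_bp` along the locus; the
#' value at bin `(u, v)` is the median of normalised contacts over
#' unmasked primer pairs whose midpoints fall in
#' `[u - window_bp/2, u + window_bp/2)` on each axis. Contacts enter
#' symmetrically (a forward-at-x / reverse-at-y contact supports both
#' `(x, y)` and `(y, x)`), so the binned map is symmetric by
#' construction. Bins supported by fewer than `min_pairs` distinct primer
#' pairs are invalid.
#'
#' @param map A normalised, masked `raw_contact_map`.
#' @param length_bp Locus length defining the bin grid (defaults to the
#'   largest primer end).
#' @param window_bp Running window (default 30 kb).
#' @param resolution_bp Grid step / final resolution (default 6 kb).
#' @param min_pairs Minimum distinct supporting pairs per bin.
#' @param midpoints_fwd,midpoints_rev Optional overrides for the primer
#'   midpoints used to place contacts on the grid (used to bin a
#'   mutant-allele map on reference coordinates).
#' @return A `binned_map`: `values`, `valid`, `n_pairs` (bin x bin
#'   matrices), `bin_starts`, `resolution_bp`, `window_bp`.
#' @export
bin_running_median <- function(map, length_bp = NULL, window_bp = 30000,
                               resolution_bp = 6000, min_pairs = 3,
                               midpoints_fwd = NULL, midpoints_rev = NULL) {
  stopifnot(inherits(map, "raw_contact_map"))
  if (!isTRUE(map$normalized)) stop("normalise the map first")
  if (window_bp < resolution_bp)
    stop("window_bp must be >= resolution_bp")
  mf <- if (is.null(midpoints_fwd)) map$fwd$midpoint else midpoints_fwd
  mr <- if (is.null(midpoints_rev)) map$rev$midpoint else midpoints_rev
  if (is.null(length_bp))
    length_bp <- max(map$fwd$end, map$rev$end, mf, mr)
  anchors <- seq(0, length_bp - 1, by = resolution_bp)
  nb <- length(anchors)

  v <- map$values
  ok <- which(!is.na(v), arr.ind = TRUE)
  half <- window_bp / 2

  # symmetrised contact points (locus1, locus2, value, pair id)
  pts <- data.table::data.table(
    m1 = c(mf[ok[, 1L]], mr[ok[, 2L]]),
    m2 = c(mr[ok[, 2L]], mf[ok[, 1L]]),
    val = rep(v[ok], 2L),
    pair = rep(seq_len(nrow(ok)), 2L))

  # anchors u with m in [u - half, u + half): u in (m - half, m + half]
  expand <- function(m) {
    lo <- as.integer(floor((m - half) / resolution_bp)) + 1L  # 0-based
    hi <- as.integer(floor((m + half) / resolution_bp))
    lo <- pmax(lo, 0L); hi <- pmin(hi, nb - 1L)
    list(lo = lo, hi = hi, n = pmax(hi - lo + 1L, 0L))
  }
  e1 <- expand(pts$m1)
  keep <- e1$n > 0
  pts <- pts[keep]; lo1 <- e1$lo[keep]; n1 <- e1$n[keep]
  idx <- rep(seq_len(nrow(pts)), n1)
  anchor_u <- sequence(n1, from = as.integer(lo1) + 1L) - 1L
  pts2 <- pts[idx]
  data.table::set(pts2, j = "u", value = anchor_u)
  e2 <- expand(pts2$m2)
  keep <- e2$n > 0
  pts2 <- pts2[keep]; lo2 <- e2$lo[keep]; n2 <- e2$n[keep]
  idx <- rep(seq_len(nrow(pts2)), n2)
  anchor_w <- sequence(n2, from = as.integer(lo2) + 1L) - 1L
  cells <- pts2[idx]
  data.table::set(cells, j = "w", value = anchor_w)

  val <- pair <- NULL  # appease R CMD check
  # plain median() keeps data.table's grouped-median fast path (GForce)
  agg <- cells[, list(med = median(val)), by = c("u", "w")]
  supp <- unique(cells, by = c("u", "w", "pair"))[, list(n = .N),
                                                  by = c("u", "w")]

  values <- matrix(NA_real_, nb, nb)
  npairs <- matrix(0L, nb, nb)
  values[cbind(agg$u + 1L, agg$w + 1L)] <- agg$med
  npairs[cbind(supp$u + 1L, supp$w + 1L)] <- supp$n
  valid <- npairs >= min_pairs
  values[!valid] <- NA_real_

  structure(list(values = values, valid = valid, n_pairs = npairs,
                 bin_starts = anchors, resolution_bp = resolution_bp,
                 window_bp = window_bp),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  cat(sprintf("<binned_map> %d x %d bins at %d bp (window %d bp), %d%% valid\n",
              nrow(x$values), ncol(x$values), x$resolution_bp, x$window_bp,
              round(100 * mean(x$valid))))
  invisible(x)
}

#' Neighbourhood coefficient-of-variation noise mask
#'
#' Chromatin behaves as a polymer, so the contact frequency of a locus
#' pair cannot differ wildly from that of its immediate neighbours; a
#' pixel whose value is very different from the surrounding contacts is
#' noise. For every pixel the coefficient of variation (sample sd / mean)
#' of the valid pixels in a `square_size` x `square_size` square around it
#' is computed; pixels with CV above `threshold` are masked. For the
#' default even square the window covers offsets `-5..+4` on both axes
#' (clipped at the matrix edges). Pixels whose square holds fewer than 4
#' valid pixels or has mean 0 are masked as unsupported.
#'
#' @param binned A `binned_map`.
#' @param square_size Side of the square in bins (default 10).
#' @param threshold CV threshold (default 1; see [cv_distribution()]).
#' @return A `cv_mask`: `cv` (matrix, NA where undefined), `masked`
#'   (logical matrix over valid pixels), `threshold`, `square_size`.
#' @export
neighborhood_cv_mask <- function(binned, square_size = 10, threshold = 1.0) {
  stopifnot(inherits(binned, "binned_map"))
  if (square_size < 2) stop("square_size must be >= 2")
  v <- binned$values
  nr <- nrow(v); nc <- ncol(v)
  lo <- -floor(square_size / 2)
  offsets <- seq(lo, length.out = square_size)

  s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0L, nr, nc)
  for (di in offsets) for (dj in offsets) {
    src_r <- seq_len(nr) + di; src_c <- seq_len(nc) + dj
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    sub <- v[src_r[ok_r], src_c[ok_c], drop = FALSE]
    has <- !is.na(sub)
    t1 <- s1[ok_r, ok_c, drop = FALSE]; t1[has] <- t1[has] + sub[has]
    s1[ok_r, ok_c] <- t1
    t2 <- s2[ok_r, ok_c, drop = FALSE]; t2[has] <- t2[has] + sub[has]^2
    s2[ok_r, ok_c] <- t2
    tn <- n[ok_r, ok_c, drop = FALSE]; tn[has] <- tn[has] + 1L
    n[ok_r, ok_c] <- tn
  }
  mean_ <- ifelse(n > 0, s1 / n, NA_real_)
  var_ <- ifelse(n > 1, pmax(s2 - s1^2 / n, 0) / (n - 1), NA_real_)
  cv <- ifelse(!is.na(mean_) & mean_ > 0, sqrt(var_) / mean_, NA_real_)

  unsupported <- n < 4 | is.na(mean_) | mean_ <= 0
  masked <- binned$valid & (unsupported | (!is.na(cv) & cv > threshold))
  cv[!binned$valid] <- NA_real_
  structure(list(cv = cv, masked = masked, threshold = threshold,
                 square_size = square_size),
            class = "cv_mask")
}

#' Distribution of neighbourhood CV values and a suggested threshold
#'
#' Diagnostic companion to [neighborhood_cv_mask()]: histogram of the CV
#' values and, when the kernel-smoothed density is bimodal, the deepest
#' internal valley as a suggested threshold (the study observed a bimodal
#' CV distribution around 1 and set the threshold there). The suggestion
#' is never applied automatically.
#'
#' @param binned A `binned_map`.
#' @param square_size,breaks Passed to the CV computation / histogram.
#' @return A list: `histogram` (counts/mids), `suggested_threshold`,
#'   `unimodal` flag, `cv` (the raw CV values).
#' @export
cv_distribution <- function(binned, square_size = 10, breaks = 50) {
  cvm <- neighborhood_cv_mask(binned, square_size, threshold = Inf)
  cv <- cvm$cv[!is.na(cvm$cv)]
  if (length(cv) == 0L)
    return(list(histogram = NULL, suggested_threshold = 1.0,
                unimodal = NA, cv = numeric(0)))
  h <- graphics::hist(cv, breaks = breaks, plot = FALSE)
  if (length(cv) < 10L || stats::sd(cv) == 0)
    return(list(histogram = h, suggested_threshold = 1.0,
                unimodal = TRUE, cv = cv))
  d <- stats::density(cv)
  y <- d$y
  minima <- which(diff(sign(diff(y))) == 2) + 1L
  # a valley only counts if both flanking peaks rise to at least twice
  # its density - shallow wiggles of the kernel estimate are not modes
  depth_ok <- vapply(minima, function(i) {
    left <- max(y[seq_len(i - 1L)])
    right <- max(y[seq(i + 1L, length(y))])
    min(left, right) >= 2 * y[i]
  }, logical(1))
  minima <- minima[depth_ok]
  if (length(minima) == 0L)
    return(list(histogram = h, suggested_threshold = 1.0,
                unimodal = TRUE, cv = cv))
  valley <- minima[which.min(y[minima])]
  list(histogram = h, suggested_threshold = d$x[valley],
       unimodal = FALSE, cv = cv)
}

#' Distance-stratified z-score map
#'
#' 5C signal is dominated by the genomic-distance decay, so z-scores are
#' computed within distance strata: pixels are grouped by their pairwise
#' genomic separation (by default the bin-grid distance `|u - v|`), and
#' within each stratum `z = (log1p(value) - mean) / sd` over valid,
#' CV-unmasked pixels. Strata are keyed by the (rounded-bp) separation
#' value itself, so externally supplied separations - e.g. the
#' deletion-adjusted distances of [deletion_adjust()] - place
#' rearrangement-spanning pixels in their own post-rearrangement strata;
#' the distance adjustment is thereby performed along with the z-score
#' calculation. Strata with fewer than `min_stratum` pixels or zero sd
#' are degenerate: their z is 0 and they are flagged.
#'
#' @param binned A `binned_map`.
#' @param cv_mask Optional `cv_mask` from [neighborhood_cv_mask()].
#' @param distances Optional bin x bin matrix of genomic separations in
#'   bp (NA drops a pixel); defaults to the grid distance.
#' @param min_stratum Minimum pixels per stratum (default 3).
#' @param log_transform Use log1p values (default TRUE); FALSE z-scores
#'   the raw values.
#' @return A `zscore_map`: `z` (matrix, NA off-mask), `strata` (matrix of
#'   stratum keys), `valid`, `degenerate` (logical matrix of pixels in
#'   degenerate strata).
#' @export
distance_zscore <- function(binned, cv_mask = NULL, distances = NULL,
                            min_stratum = 3, log_transform = TRUE) {
  stopifnot(inherits(binned, "binned_map"))
  nb <- nrow(binned$values)
  if (is.null(distances)) {
    idx <- seq_len(nb) - 1L
    distances <- abs(outer(idx, idx, "-")) * binned$resolution_bp
  }
  if (!all(dim(distances) == dim(binned$values)))
    stop("distance matrix does not match the bin grid")
  valid <- binned$valid & !is.na(distances)
  if (!is.null(cv_mask)) valid <- valid & !cv_mask$masked
  strata <- round(distances)

  x <- if (log_transform) log1p(binned$values) else binned$values
  z <- matrix(NA_real_, nb, nb)
  degen <- matrix(FALSE, nb, nb)
  keys <- strata[valid]
  vals <- x[valid]
  pos <- which(valid)
  for (s in split(seq_along(pos), keys)) {
    xv <- vals[s]
    sdev <- stats::sd(xv)
    if (length(s) < min_stratum || is.na(sdev) || sdev < 1e-12) {
      z[pos[s]] <- 0
      degen[pos[s]] <- TRUE
    } else {
      z[pos[s]] <- (xv - mean(xv)) / sdev
    }
  }
  structure(list(z = z, strata = strata, valid = valid,
                 degenerate = degen),
            class = "zscore_map")
}
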