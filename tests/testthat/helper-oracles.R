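# Independent brute-force oracles and small fixture builders.
# The oracles deliberately share no code with the implementation: plain
# loops, two-pass statistics, pairwise-count U statistics.

# A raw contact map with arbitrary midpoints and pre-normalised values.
rand_raw_map <- function(n_fwd, n_rev, length_bp, seed,
                         na_frac = 0) {
  set.seed(seed)
  n <- n_fwd + n_rev
  mids <- sort(sample(seq(500, length_bp - 500, by = 250), n))
  cat_ <- rep_len(c("forward", "reverse"), n)
  prim <- data.frame(
    primer_id = sprintf("%s_%d", ifelse(cat_ == "forward", "F", "R"),
                        seq_len(n)),
    fragment = seq_len(n), start = mids - 15, end = mids + 15,
    midpoint = mids, category = cat_, sequence = NA_character_,
    efficient = TRUE, stringsAsFactors = FALSE)
  fwd <- prim[prim$category == "forward", ][seq_len(n_fwd), ]
  rev <- prim[prim$category == "reverse", ][seq_len(n_rev), ]
  vals <- matrix(stats::rexp(n_fwd * n_rev, rate = 0.01), n_fwd, n_rev,
                 dimnames = list(fwd$primer_id, rev$primer_id))
  if (na_frac > 0)
    vals[sample(length(vals), round(na_frac * length(vals)))] <- NA
  m <- xic5c:::new_raw_contact_map(round(vals), fwd, rev)
  m$values <- vals
  m$normalized <- TRUE
  m
}

# A binned_map built directly from a value matrix.
as_binned <- function(values, resolution_bp = 6000, valid = NULL) {
  nb <- nrow(values)
  if (is.null(valid)) valid <- !is.na(values)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 n_pairs = matrix(10L, nb, nb),
                 bin_starts = seq(0, by = resolution_bp,
                                  length.out = nb),
                 resolution_bp = resolution_bp,
                 window_bp = 5 * resolution_bp),
            class = "binned_map")
}

rand_binned <- function(nb, seed, na_frac = 0.1, resolution_bp = 6000) {
  set.seed(seed)
  v <- matrix(stats::rexp(nb * nb, 0.05), nb, nb)
  v <- (v + t(v)) / 2
  valid <- matrix(stats::runif(nb * nb) > na_frac, nb, nb)
  valid <- valid & t(valid)
  as_binned(v, resolution_bp, valid)
}

# Expected-matrix map wrapper: treats lambda as normalised values.
lambda_as_map <- function(sim) {
  m <- sim$map
  m$values <- sim$lambda * 1e6 / sum(sim$lambda)
  m$normalized <- TRUE
  m
}

# --- oracle: running-median binning -------------------------------------
oracle_bin <- function(map, length_bp, window_bp = 30000,
                       resolution_bp = 6000, min_pairs = 3) {
  anchors <- seq(0, length_bp - 1, by = resolution_bp)
  nb <- length(anchors)
  mf <- map$fwd$midpoint; mr <- map$rev$midpoint
  v <- map$values
  values <- matrix(NA_real_, nb, nb)
  npairs <- matrix(0L, nb, nb)
  half <- window_bp / 2
  for (ui in seq_len(nb)) for (wi in seq_len(nb)) {
    u <- anchors[ui]; w <- anchors[wi]
    vals <- c(); pairs <- c()
    for (i in seq_along(mf)) for (j in seq_along(mr)) {
      if (is.na(v[i, j])) next
      # contact supports (mf, mr) and the mirrored (mr, mf)
      if (mf[i] >= u - half && mf[i] < u + half &&
          mr[j] >= w - half && mr[j] < w + half) {
        vals <- c(vals, v[i, j]); pairs <- c(pairs, paste(i, j))
      }
      if (mr[j] >= u - half && mr[j] < u + half &&
          mf[i] >= w - half && mf[i] < w + half) {
        vals <- c(vals, v[i, j]); pairs <- c(pairs, paste(i, j))
      }
    }
    npairs[ui, wi] <- length(unique(pairs))
    if (length(unique(pairs)) >= min_pairs)
      values[ui, wi] <- stats::median(vals)
  }
  list(values = values, n_pairs = npairs)
}

# --- oracle: neighbourhood CV -------------------------------------------
oracle_cv <- function(binned, square_size = 10, threshold = 1.0) {
  v <- binned$values
  nb <- nrow(v)
  lo <- -floor(square_size / 2)
  cv <- matrix(NA_real_, nb, nb)
  masked <- matrix(FALSE, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    xs <- c()
    for (di in lo:(lo + square_size - 1)) for (dj in lo:(lo + square_size - 1)) {
      r <- i + di; s <- j + dj
      if (r >= 1 && r <= nb && s >= 1 && s <= nb && !is.na(v[r, s]))
        xs <- c(xs, v[r, s])
    }
    unsupported <- length(xs) < 4 || mean(xs) <= 0
    if (length(xs) > 1 && mean(xs) > 0)
      cv[i, j] <- stats::sd(xs) / mean(xs)
    if (binned$valid[i, j])
      masked[i, j] <- unsupported ||
        (!is.na(cv[i, j]) && cv[i, j] > threshold)
    if (!binned$valid[i, j]) cv[i, j] <- NA_real_
  }
  list(cv = cv, masked = masked)
}

# --- oracle: distance-stratified z-scores --------------------------------
oracle_z <- function(binned, cv_mask = NULL, distances = NULL,
                     min_stratum = 3) {
  v <- binned$values
  nb <- nrow(v)
  if (is.null(distances)) {
    idx <- seq_len(nb) - 1
    distances <- abs(outer(idx, idx, "-")) * binned$resolution_bp
  }
  valid <- binned$valid & !is.na(distances)
  if (!is.null(cv_mask)) valid <- valid & !cv_mask$masked
  z <- matrix(NA_real_, nb, nb)
  x <- log1p(v)
  for (key in unique(round(distances[valid]))) {
    sel <- valid & round(distances) == key
    xs <- x[sel]
    if (length(xs) < min_stratum || stats::sd(xs) < 1e-12) {
      z[sel] <- 0
    } else {
      z[sel] <- (xs - mean(xs)) / stats::sd(xs)
    }
  }
  z
}

# --- oracle: Mann-Whitney by pairwise counting + value enumeration -------
oracle_mw <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  pool <- c(a, b)
  na <- length(a)
  cmb <- utils::combn(length(pool), na)
  u_of <- function(idx) {
    aa <- pool[idx]; bb <- pool[-idx]
    s <- 0
    for (x in aa) for (y in bb) s <- s + (x > y) + 0.5 * (x == y)
    s
  }
  u_all <- apply(cmb, 2, u_of)
  p <- min(1, 2 * min(mean(u_all <= u + 1e-9), mean(u_all >= u - 1e-9)))
  list(u = u, p = p)
}
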