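make_sim_map <- function(seed = 1, depth = 5e4) {
  lp <- make_layout(120000, 20, 30, seed = seed)
  sim <- simulate_contact_map(lp$primers, NULL, numeric(0),
                              sim_params(depth = depth, seed = seed))
  list(lp = lp, map = sim$map)
}

test_that("pooling sums replicates and scales to exactly one million", {
  s <- make_sim_map(1)
  one <- pool_and_normalize(s$map)
  expect_equal(sum(one$values, na.rm = TRUE), 1e6)

  two <- pool_and_normalize(list(s$map, s$map))
  expect_equal(two$counts, s$map$counts + s$map$counts)
  expect_equal(two$values, one$values)   # scaling removes the doubling

  zero <- s$map
  zero$counts[] <- 0L
  expect_error(pool_and_normalize(zero), "degenerate")

  other <- make_sim_map(2)$map
  other$fwd$primer_id[1] <- "X_99"
  expect_error(pool_and_normalize(list(s$map, other)), "primer sets")
})

test_that("masked primers are excluded from the normalisation total", {
  s <- make_sim_map(3)
  m <- discard_primers(s$map, flag_list = "F_1")
  nm <- pool_and_normalize(m)
  expect_true(all(is.na(nm$values[1, ])))
  expect_equal(sum(nm$values, na.rm = TRUE), 1e6)
})

test_that("outlier probes and singleton pixels are filtered", {
  s <- make_sim_map(4)
  nm <- pool_and_normalize(s$map)

  flat <- nm
  flat$values[] <- 10
  flat$values <- flat$values * 1e6 / sum(flat$values)
  out <- filter_outliers_singletons(flat)
  expect_true(all(out$fwd_mask) && all(out$rev_mask))
  expect_false(any(out$pixel_mask))

  # one 1000x spike on an otherwise flat map is a singleton
  spike <- flat
  spike$values[5, 5] <- spike$values[5, 5] * 1000
  out2 <- filter_outliers_singletons(spike)
  expect_true(out2$pixel_mask[5, 5])
  expect_equal(sum(out2$pixel_mask), 1L)

  # a primer with 100x its expected total is an outlier probe (on a map
  # large enough that the spill-over into column totals stays moderate)
  lp <- make_layout(600000, 100, 30, seed = 4)
  sim <- simulate_contact_map(lp$primers, NULL, numeric(0),
                              sim_params(depth = 5e5, seed = 4))
  hot <- pool_and_normalize(sim$map)
  hot$values[3, ] <- hot$values[3, ] * 100
  out3 <- filter_outliers_singletons(hot)
  expect_false(out3$fwd_mask[3])
  expect_true(all(out3$fwd_mask[-3]))
})

test_that("running-median binning matches the brute-force oracle", {
  # hand-checkable toy: 12 primers
  m <- rand_raw_map(6, 6, 72000, seed = 11)
  bm <- bin_running_median(m, length_bp = 72000)
  ob <- oracle_bin(m, 72000)
  expect_equal(bm$values, ob$values)
  expect_equal(bm$n_pairs, ob$n_pairs)
  expect_equal(bm$valid, ob$n_pairs >= 3)

  # randomised equivalence incl. masked values
  for (s in 1:6) {
    m <- rand_raw_map(5, 5, 48000, seed = 100 + s, na_frac = 0.2)
    bm <- bin_running_median(m, length_bp = 48000, min_pairs = 2)
    ob <- oracle_bin(m, 48000, min_pairs = 2)
    expect_equal(bm$values, ob$values)
    expect_equal(bm$n_pairs, ob$n_pairs)
  }

  expect_error(bin_running_median(m, window_bp = 100, resolution_bp = 6000),
               "window")
})

test_that("binning is symmetric, monotone under scaling, NA off-support", {
  m <- rand_raw_map(8, 8, 96000, seed = 12)
  bm <- bin_running_median(m, length_bp = 96000)
  expect_equal(bm$values, t(bm$values))

  m2 <- m
  m2$values <- m$values * 3.5
  bm2 <- bin_running_median(m2, length_bp = 96000)
  expect_equal(bm2$values, bm$values * 3.5)

  # a window over empty territory is invalid
  far <- bin_running_median(m, length_bp = 300000)
  expect_false(any(far$valid[40:50, 40:50]))
})

test_that("constant maps bin to a constant and get CV zero", {
  m <- rand_raw_map(6, 6, 72000, seed = 13)
  m$values[] <- 42
  bm <- bin_running_median(m, length_bp = 72000)
  expect_true(all(bm$values[bm$valid] == 42))
  cvm <- neighborhood_cv_mask(bm)
  expect_true(all(cvm$cv[bm$valid] == 0, na.rm = TRUE))
  expect_false(any(cvm$masked))
})

test_that("neighbourhood CV mask matches the per-pixel oracle", {
  for (s in 1:10) {
    bm <- rand_binned(20, seed = 200 + s, na_frac = 0.15)
    cvm <- neighborhood_cv_mask(bm)
    ocv <- oracle_cv(bm)
    expect_equal(cvm$masked, ocv$masked)
    expect_equal(cvm$cv, ocv$cv, tolerance = 1e-10)
  }
  expect_error(neighborhood_cv_mask(rand_binned(20, 1), square_size = 1),
               "square_size")
})

test_that("CV mask is scale-free and threshold 0 masks any variation", {
  bm <- rand_binned(20, seed = 31, na_frac = 0)
  cvm <- neighborhood_cv_mask(bm)
  bm2 <- bm
  bm2$values <- bm$values * 7
  expect_equal(neighborhood_cv_mask(bm2)$masked, cvm$masked)
  expect_equal(neighborhood_cv_mask(bm2)$cv, cvm$cv, tolerance = 1e-12)

  all_masked <- neighborhood_cv_mask(bm, threshold = 0)
  expect_true(all(all_masked$masked[bm$valid][
    !is.na(all_masked$cv[bm$valid]) & all_masked$cv[bm$valid] > 0]))
})

test_that("cv_distribution finds the valley of a bimodal CV field", {
  # two blocks: one near-constant (low CV), one wildly varying (high CV)
  set.seed(42)
  nb <- 40
  v <- matrix(100 + stats::rnorm(nb * nb, 0, 18), nb, nb)  # CV ~ 0.18
  hi <- matrix(stats::rexp(400, 1 / 100) * stats::rbinom(400, 1, 0.3),
               20, 20)                                     # CV >> 1
  v[21:40, 21:40] <- hi
  bm <- as_binned(abs(v))
  res <- cv_distribution(bm)
  expect_false(res$unimodal)
  expect_gt(res$suggested_threshold, min(res$cv))
  expect_lt(res$suggested_threshold, max(res$cv))

  flat <- as_binned(matrix(50 + stats::rnorm(400, 0, 5), 20, 20))
  res2 <- cv_distribution(flat)
  expect_true(res2$unimodal)
  expect_equal(res2$suggested_threshold, 1.0)

  empty <- as_binned(matrix(NA_real_, 12, 12))
  res3 <- cv_distribution(empty)
  expect_equal(res3$suggested_threshold, 1.0)
  expect_equal(length(res3$cv), 0L)
})

test_that("distance z-scores are exactly standardised within strata", {
  for (s in 1:5) {
    bm <- rand_binned(30, seed = 300 + s)
    cvm <- neighborhood_cv_mask(bm)
    zs <- distance_zscore(bm, cvm)
    ok <- zs$valid & !zs$degenerate
    for (key in unique(zs$strata[ok])) {
      zz <- zs$z[ok & zs$strata == key]
      expect_lt(abs(mean(zz)), 1e-9)
      expect_lt(abs(stats::sd(zz) - 1), 1e-9)
    }
    # full-map oracle equivalence
    expect_equal(zs$z[ok], oracle_z(bm, cvm)[ok], tolerance = 1e-12)
  }
})

test_that("noise-free power-law maps are degenerate everywhere (z = 0)", {
  # every stratum of a pure distance-decay map is constant, so the
  # degenerate rule zeroes the whole z map
  idx <- 0:29
  decay <- (abs(outer(idx, idx, "-")) * 6000 + 3000)^-1
  zs <- distance_zscore(as_binned(decay * 1e6))
  expect_true(all(zs$z[zs$valid] == 0))
  expect_true(all(zs$degenerate[zs$valid]))
})

test_that("z maps converge under global rescaling of a large-valued map", {
  bm <- rand_binned(30, seed = 77)
  bm$values <- bm$values * 50 + 100   # values >> 1
  z1 <- distance_zscore(bm)
  bm2 <- bm
  bm2$values <- bm$values * 2
  z2 <- distance_zscore(bm2)
  ok <- z1$valid & !z1$degenerate
  expect_lt(max(abs(z1$z[ok] - z2$z[ok])), 0.05)
})
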