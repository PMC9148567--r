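test_that("make_layout tiles the locus with an alternating primer set", {
  lp <- make_layout(300000, 50, 30, seed = 7)
  expect_equal(length(lp$layout$fragment_bounds), 51L)
  expect_equal(lp$layout$fragment_bounds[1], 0)
  expect_equal(lp$layout$fragment_bounds[51], 300000)
  expect_true(all(diff(lp$layout$fragment_bounds) > 0))
  expect_equal(sum(lp$primers$category == "forward"), 25L)
  expect_equal(sum(lp$primers$category == "reverse"), 25L)
  # every primer inside its fragment
  expect_true(all(lp$primers$start >=
                    lp$layout$fragment_bounds[lp$primers$fragment]))
  expect_true(all(lp$primers$end <=
                    lp$layout$fragment_bounds[lp$primers$fragment + 1L]))
  # determinism
  expect_identical(lp, make_layout(300000, 50, 30, seed = 7))
  # distinct sequences
  expect_false(anyDuplicated(lp$primers$sequence) > 0)
})

test_that("make_layout rejects degenerate arguments", {
  expect_error(make_layout(300000, 1, 30, 7), "n_fragments")
  expect_error(make_layout(-5, 10, 30, 7), "length_bp")
  expect_error(make_layout(300, 10, 30, 7), "primer_len")
})

test_that("expected contact matrix follows the programmed model", {
  lp <- make_layout(240000, 40, 30, seed = 2)
  p <- sim_params(decay_exponent = 1, depth = 1e5, tad_factor = 1,
                  cross_boundary_factor = 1, loop_strength = 0)
  sim <- simulate_contact_map(lp$primers, NULL, numeric(0), p)
  expect_equal(sum(sim$lambda), p$depth)
  # pure power law with alpha = 1: tripling the separation divides the
  # expected contact by 3 (forward-reverse separations on the alternating
  # grid are odd multiples of 6 kb, so 6 kb vs 18 kb is the clean pair)
  d <- abs(outer(sim$map$fwd$midpoint, sim$map$rev$midpoint, "-"))
  l6 <- sim$lambda[which(d == 6000)[1]]
  l18 <- sim$lambda[which(d == 18000)[1]]
  expect_equal(l6 / l18, 3)

  # convergent pair boosts its pixel by 1 + loop_strength at strength 1;
  # a tandem pair leaves the map loop-free (sites sit on the midpoints of
  # a forward and a reverse primer)
  sites_conv <- ctcf_sites(c(63000, 177000), c("right", "left"), 1)
  sites_tand <- ctcf_sites(c(63000, 177000), c("left", "left"), 1)
  pl <- sim_params(decay_exponent = 1, depth = 1e5, tad_factor = 1,
                   cross_boundary_factor = 1, loop_strength = 3)
  s_conv <- simulate_contact_map(lp$primers, sites_conv, numeric(0), pl)
  s_tand <- simulate_contact_map(lp$primers, sites_tand, numeric(0), pl)
  expect_equal(nrow(s_conv$loops), 1L)
  expect_equal(s_conv$loops$factor, 4)
  expect_equal(nrow(s_tand$loops), 0L)
  i <- s_conv$loops$fwd; j <- s_conv$loops$rev
  # equal-distance pixel ratio = 4 before renormalisation; compare
  # unnormalised ratios through a same-distance reference pixel
  ref <- which(d == d[i, j] & row(d) != i, arr.ind = TRUE)[1, ]
  ratio <- (s_conv$lambda[i, j] / s_conv$lambda[ref[1], ref[2]]) /
    (s_tand$lambda[i, j] / s_tand$lambda[ref[1], ref[2]])
  expect_equal(ratio, 4)
})

test_that("Poisson counts match their expectation across seeds", {
  lp <- make_layout(60000, 10, 30, seed = 3)
  acc <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    p <- sim_params(decay_exponent = 1, depth = 2e4, seed = s)
    sim <- simulate_contact_map(lp$primers, NULL, numeric(0), p)
    if (s == 1) lam <- sim$lambda
    acc <- acc + sim$map$counts
  }
  mean_k <- acc / n_rep
  se <- sqrt(lam / n_rep)
  expect_true(all(abs(mean_k - lam) <= 3 * se + 1e-9))
})

test_that("Poisson dispersion index is near 1 for well-covered pixels", {
  lp <- make_layout(60000, 10, 30, seed = 3)
  n_rep <- 200
  draws <- array(NA_real_, c(5, 5, n_rep))
  for (s in seq_len(n_rep)) {
    p <- sim_params(decay_exponent = 1, depth = 2e4, seed = 5000 + s)
    sim <- simulate_contact_map(lp$primers, NULL, numeric(0), p)
    if (s == 1) lam <- sim$lambda
    draws[, , s] <- sim$map$counts
  }
  m <- apply(draws, c(1, 2), mean)
  v <- apply(draws, c(1, 2), var)
  idx <- lam >= 5
  disp <- (v / m)[idx]
  expect_true(all(disp > 0.8 & disp < 1.2))
})

test_that("inversion reflects and flips CTCF sites and is an involution", {
  lp <- make_layout(300000, 50, 30, seed = 1)
  sites <- ctcf_sites(150, "right", 1)
  spec <- rearrangement_spec("inversion", 100, 200)
  out <- apply_rearrangement(
    structure(list(chrom = "c", length_bp = 300,
                   fragment_bounds = c(0, 100, 200, 300)),
              class = "fivec_layout"), sites, spec)
  expect_equal(out$sites$position, 149)
  expect_equal(out$sites$orientation, "left")

  sites2 <- ctcf_sites(c(78000, 180000, 288000),
                       c("right", "left", "left"), c(1.5, 1, 1))
  spec2 <- rearrangement_spec("inversion", 30000, 270000)
  once <- apply_rearrangement(lp$layout, sites2, spec2)
  twice <- apply_rearrangement(once$layout, once$sites, spec2)
  expect_equal(twice$layout$fragment_bounds, lp$layout$fragment_bounds)
  expect_equal(twice$sites$position, sites2$position)
  expect_equal(twice$sites$orientation, sites2$orientation)
})

test_that("deletion removes and shifts sites and shrinks the genome", {
  lay <- structure(list(chrom = "c", length_bp = 400,
                        fragment_bounds = c(0, 100, 200, 300, 400)),
                   class = "fivec_layout")
  sites <- ctcf_sites(c(150, 250), c("right", "left"), 1)
  out <- apply_rearrangement(lay, sites,
                             rearrangement_spec("deletion", 100, 200))
  expect_equal(out$sites$position, 150)   # 250 shifted by -100
  expect_equal(nrow(out$sites), 1L)       # 150 removed
  expect_equal(out$layout$length_bp, 300)
  expect_error(
    apply_rearrangement(lay, sites, rearrangement_spec("deletion", 300, 500)),
    "outside")
})

test_that("printed clone-1 breakpoints give the published segment sizes", {
  inv <- rearrangement_spec("inversion", 100377328, 100622017, "mm9")
  expect_equal(inv$length_bp, 244689)
  expect_equal(round(inv$length_bp / 1000), 245)
  del <- rearrangement_spec("deletion", 103370850, 103384956, "mm10")
  expect_equal(del$length_bp, 14106)
  expect_equal(round(del$length_bp / 1000), 14)
})

test_that("junction reads follow the contact map and are reproducible", {
  lp <- make_layout(60000, 10, 30, seed = 4)
  p <- sim_params(depth = 1e4, seed = 1)
  sim <- simulate_contact_map(lp$primers, NULL, numeric(0), p)

  single <- sim$map
  single$counts[] <- 0L
  single$counts[2, 3] <- 5L
  reads <- simulate_junction_reads(single, 50, seed = 9)
  expect_true(all(reads == paste0(single$fwd$sequence[2],
                                  single$rev$sequence[3])))

  r1 <- simulate_junction_reads(sim$map, 500, seed = 11)
  r2 <- simulate_junction_reads(sim$map, 500, seed = 11)
  expect_identical(r1, r2)

  # multinomial agreement at n = 10,000
  n <- 10000
  reads <- simulate_junction_reads(sim$map, n, seed = 21)
  ids <- sub("^read_[0-9]+\\|", "", names(reads))
  pr <- as.vector(sim$map$counts) / sum(sim$map$counts)
  key <- as.vector(outer(sim$map$fwd$primer_id, sim$map$rev$primer_id,
                         paste, sep = "|"))
  obs <- as.vector(table(factor(ids, levels = key)))
  se <- sqrt(n * pr * (1 - pr))
  expect_true(all(abs(obs - n * pr) <= 3 * se + 3))
})

test_that("nCounter generator honours effects, lanes and noise level", {
  base <- c(pos1 = 500, hk1 = 800, g1 = 1000, g2 = 300)
  roles <- c(pos1 = "positive_control", hk1 = "housekeeping",
             g1 = "target", g2 = "target")
  em <- simulate_ncounter(base, roles, c("s1", "s2"), cv_noise = 0)
  expect_true(all(em$counts[, 1] == em$counts[, 2]))

  eff <- matrix(1, 4, 2, dimnames = list(names(base), NULL))
  eff["g1", 2] <- 2
  em2 <- simulate_ncounter(base, roles, c("s1", "s2"), effects = eff,
                           cv_noise = 0)
  expect_equal(em2$counts["g1", 2] / em2$counts["g1", 1], 2)
  expect_error(simulate_ncounter(c(pos1 = -1, hk1 = 1), roles[1:2], "s1"),
               "baselines")
})

test_that("allelic ratio generator is truncated and calibrated", {
  a <- simulate_allelic(20, 0.5, 0, seed = 1)
  expect_true(all(a$ratio == 0.5))
  b <- simulate_allelic(500, 0.9, 0.3, seed = 2)
  expect_true(all(b$ratio >= 0 & b$ratio <= 1))
  cl <- simulate_allelic(1000, 0.5, 0.05, seed = 3)
  expect_lt(abs(mean(cl$ratio) - 0.5), 3 * 0.05 / sqrt(1000))
  expect_error(simulate_allelic(10, 1.5, 0.1), "mean_ratio")
})
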