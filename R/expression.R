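#' Gene x sample expression count container
#'
#' @param counts Non-negative gene x sample matrix with row and column
#'   names.
#' @param roles Named character vector over genes with values in
#'   `"target"`, `"positive_control"`, `"housekeeping"`; at least one
#'   positive-control and one housekeeping gene are required.
#' @param samples Optional data.frame of sample metadata with a
#'   `sample_id` column matching `colnames(counts)`.
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, roles, samples = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (any(counts < 0)) stop("counts must be >= 0")
  roles <- roles[rownames(counts)]
  if (anyNA(roles)) stop("every gene needs a role annotation")
  if (!all(roles %in% c("target", "positive_control", "housekeeping")))
    stop("roles must be target/positive_control/housekeeping")
  if (!any(roles == "positive_control"))
    stop("at least one positive_control gene is required")
  if (!any(roles == "housekeeping"))
    stop("at least one housekeeping gene is required")
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(counts),
                          stringsAsFactors = FALSE)
  structure(list(counts = counts, roles = roles, samples = samples),
            class = "expression_matrix")
}

#' Simulate an nCounter-style expression experiment
#'
#' Expected count of gene `g` in sample `s` is
#' `baseline[g] * effect[g, s] * lane_scale[s]`, with multiplicative
#' log-normal noise of the stated coefficient of variation (mean-one, so
#' `cv_noise = 0` reproduces the expectation exactly). Positive-control
#' and housekeeping genes always carry effect 1, which is what makes the
#' two-step control normalisation of [normalize_ncounter()] able to undo
#' the per-lane scale factors.
#'
#' @param baselines Named non-negative numeric vector of per-gene baseline
#'   counts.
#' @param roles Named role vector as in [expression_matrix()].
#' @param sample_ids Character vector of sample names.
#' @param lane_scale Per-sample technical scale factors (recycled).
#' @param effects Gene x sample matrix of fold effects (default all 1);
#'   rows for control genes are overridden to 1.
#' @param cv_noise Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param samples Optional sample metadata data.frame.
#' @return An `expression_matrix`.
#' @export
simulate_ncounter <- function(baselines, roles, sample_ids,
                              lane_scale = 1, effects = NULL,
                              cv_noise = 0.1, seed = 1L, samples = NULL) {
  if (any(baselines < 0)) stop("baselines must be >= 0")
  if (cv_noise < 0) stop("cv_noise must be >= 0")
  g <- names(baselines)
  ns <- length(sample_ids)
  lane_scale <- rep_len(lane_scale, ns)
  if (is.null(effects)) effects <- matrix(1, length(g), ns)
  if (!all(dim(effects) == c(length(g), ns)))
    stop("effects must be a gene x sample matrix")
  effects[roles[g] != "target", ] <- 1
  expected <- baselines * effects * rep(lane_scale, each = length(g))
  set.seed(as.integer(seed))
  if (cv_noise > 0) {
    sigma <- sqrt(log(1 + cv_noise^2))
    noise <- exp(matrix(stats::rnorm(length(expected), 0, sigma),
                        length(g)) - sigma^2 / 2)
    expected <- expected * noise
  }
  dimnames(expected) <- list(g, sample_ids)
  expression_matrix(expected, roles, samples)
}

geo_mean <- function(x) exp(mean(log(x)))

#' Two-step control normalisation of nCounter counts
#'
#' Per sample, a first scale factor equates the geometric mean of the
#' positive-control genes to the across-sample mean of those geometric
#' means; a second factor then does the same on the housekeeping genes of
#' the rescaled matrix. The composition is idempotent: renormalising a
#' normalised matrix gives factors of 1.
#'
#' @param x An `expression_matrix`.
#' @return The `expression_matrix` with scaled counts and an added
#'   `norm_factors` data.frame (sample, positive-control factor,
#'   housekeeping factor).
#' @export
normalize_ncounter <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  counts <- x$counts
  step <- function(counts, which_genes, label) {
    gm <- apply(counts[which_genes, , drop = FALSE], 2, geo_mean)
    if (any(gm == 0) || anyNA(gm))
      stop("zero ", label, " geometric mean in sample ",
           colnames(counts)[which(gm == 0 | is.na(gm))[1L]])
    f <- mean(gm) / gm
    list(counts = sweep(counts, 2, f, "*"), f = f)
  }
  s1 <- step(counts, x$roles == "positive_control", "positive-control")
  s2 <- step(s1$counts, x$roles == "housekeeping", "housekeeping")
  out <- x
  out$counts <- s2$counts
  out$norm_factors <- data.frame(sample_id = colnames(counts),
                                 positive_control = s1$f,
                                 housekeeping = s2$f)
  out
}

#' Per-gene expression relative to a reference sample
#'
#' @param x A (normalised) `expression_matrix`.
#' @param reference_sample Column name of the reference sample (the study
#'   normalises each gene to wild-type day 0).
#' @return A list with `relative` (gene x sample matrix of ratios to the
#'   reference) and `flagged` (genes with a zero reference value, excluded
#'   from `relative`).
#' @export
fold_change_vs_reference <- function(x, reference_sample) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!reference_sample %in% colnames(x$counts))
    stop("reference sample '", reference_sample, "' not found")
  ref <- x$counts[, reference_sample]
  flagged <- rownames(x$counts)[ref == 0]
  keep <- ref > 0
  list(relative = x$counts[keep, , drop = FALSE] / ref[keep],
       flagged = flagged)
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  cut <- c(1e-4, 1e-3, 1e-2, 5e-2)
  stars <- c("****", "***", "**", "*")
  i <- which(p < cut)
  if (length(i)) stars[i[1L]] else "ns"
}

#' Two-tailed paired Student's t-test
#'
#' Matched series (e.g. per-time-point means for two genotypes across a
#' differentiation time course). Zero-variance differences yield a
#' `p_undefined` flag rather than a p-value; a series compared with itself
#' reports t = 0.
#'
#' @param series_a,series_b Equal-length numeric vectors, n >= 2, matched
#'   by position.
#' @return A list: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `p_undefined`, `stars`.
#' @export
paired_t_test <- function(series_a, series_b) {
  n <- length(series_a)
  if (n != length(series_b)) stop("series must have equal length")
  if (n < 2) stop("need at least two pairs")
  d <- series_a - series_b
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    t <- if (all(d == 0)) 0 else NA_real_
    return(list(statistic = t, df = n - 1L, p_value = NA_real_,
                mean_diff = mean(d), p_undefined = TRUE, stars = ""))
  }
  fit <- stats::t.test(series_a, series_b, paired = TRUE)
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, mean_diff = unname(fit$estimate),
       p_undefined = FALSE, stars = p_stars(fit$p.value))
}

#' Allelic ratio from two allele signals
#'
#' @param a,b Non-negative allele signals with `a + b > 0`.
#' @return `a / (a + b)`.
#' @export
allelic_ratio <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("allele signals must be >= 0")
  if (any(a + b <= 0)) stop("a + b must be > 0")
  a / (a + b)
}

# Exact permutation distribution of the rank-sum of group A
mw_exact_p <- function(u_obs, ranks, n_a) {
  n <- length(ranks)
  cmb <- utils::combn(n, n_a)
  u_all <- colSums(matrix(ranks[cmb], nrow = n_a)) - n_a * (n_a + 1) / 2
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test on allelic ratios
#'
#' U is computed from midranks. The p-value is exact (full enumeration of
#' group assignments, valid under ties) when `min(n_A, n_B) <= 8` and
#' `n_A + n_B <= 20`; otherwise the normal approximation with tie
#' correction and continuity correction is used. Two identical constant
#' groups give `U = n_A n_B / 2` and p = 1.
#'
#' @param group_a,group_b Non-empty numeric vectors (e.g. per-embryo
#'   allelic ratios for two genotype groups).
#' @return A list: `statistic` (U for group A), `p_value`, `method`,
#'   `stars`.
#' @export
allelic_ratio_test <- function(group_a, group_b) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a == 0L || n_b == 0L) stop("both groups must be non-empty")
  ranks <- rank(c(group_a, group_b))
  u <- sum(ranks[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  if (min(n_a, n_b) <= 8L && (n_a + n_b) <= 20L) {
    p <- mw_exact_p(u, ranks, n_a)
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    tie_tab <- table(ranks)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(statistic = u, p_value = min(p, 1), method = method,
       stars = p_stars(min(p, 1)))
}

#' Simulate per-embryo allelic ratios
#'
#' Pyrosequencing-style allelic ratios for one embryo cohort, drawn from a
#' normal distribution truncated to `[0, 1]`.
#'
#' @param n_embryos Number of embryos.
#' @param mean_ratio Target mean ratio in `[0, 1]`.
#' @param sd Standard deviation before truncation, >= 0.
#' @param seed Integer seed.
#' @param group Label stored in the output.
#' @param total_signal Total allele signal per embryo used to back out
#'   A/B signal columns.
#' @return A data.frame with columns `embryo_id`, `group`, `allele_a`,
#'   `allele_b`, `ratio`.
#' @export
simulate_allelic <- function(n_embryos, mean_ratio, sd, seed = 1L,
                             group = "group", total_signal = 1000) {
  if (mean_ratio < 0 || mean_ratio > 1)
    stop("mean_ratio must be in [0, 1]")
  if (sd < 0) stop("sd must be >= 0")
  set.seed(as.integer(seed))
  if (sd == 0) {
    r <- rep(mean_ratio, n_embryos)
  } else {
    r <- numeric(0)
    while (length(r) < n_embryos) {
      x <- stats::rnorm(2L * (n_embryos - length(r)), mean_ratio, sd)
      r <- c(r, x[x >= 0 & x <= 1])
    }
    r <- r[seq_len(n_embryos)]
  }
  a <- r * total_signal
  data.frame(embryo_id = sprintf("%s_e%02d", group, seq_len(n_embryos)),
             group = group, allele_a = a, allele_b = total_signal - a,
             ratio = r, stringsAsFactors = FALSE)
}
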