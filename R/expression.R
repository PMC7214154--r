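#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for a count matrix: the reference is
#' the per-feature geometric mean across samples, restricted to features
#' with no zero count; each sample's factor is the median over those
#' features of the count-to-reference ratio. This removes multiplicative
#' library-size effects while being robust to a minority of regulated
#' features.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
medianOfRatios <- function(counts) {
  counts <- .asCountMatrix(counts)
  nonzero <- rowSums(counts == 0) == 0
  if (!any(nonzero))
    stop("no feature has nonzero counts in all samples; ",
         "consider a pseudo-reference on filtered features", call. = FALSE)
  ref <- exp(rowMeans(log(counts[nonzero, , drop = FALSE])))
  sf <- apply(counts[nonzero, , drop = FALSE], 2,
              function(col) stats::median(col / ref))
  if (any(sf <= 0)) stop("non-positive size factor estimated", call. = FALSE)
  sf
}

.asCountMatrix <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  counts
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments estimate on normalized counts,
#' \code{max(0, (s^2 - mu) / mu^2)}, computed within groups when group
#' labels are given (pooled within-group variance, so planted group
#' differences do not inflate the estimate), then shrunk toward a trend
#' (the mean raw dispersion within log-mean bins) with weight
#' \code{shrinkage}. Estimates are floored at \code{floor}, which also
#' covers constant features whose sample variance is zero. The shrinkage
#' stabilizes estimates for small groups.
#'
#' @param counts count matrix (features x samples) or SummarizedExperiment.
#' @param size_factors per-sample size factors (default: median-of-ratios).
#' @param groups optional group factor, length = samples; every group must
#'   have at least 2 samples.
#' @param shrinkage weight in \code{[0, 1]} on the binned trend.
#' @param n_bins number of log-mean bins for the trend.
#' @param floor lower bound for the returned dispersions.
#' @return named numeric vector of per-feature dispersions.
#' @export
estimateDispersion <- function(counts, size_factors = NULL, groups = NULL,
                               shrinkage = 0.3, n_bins = 10L,
                               floor = 1e-8) {
  counts <- .asCountMatrix(counts)
  if (is.null(size_factors)) size_factors <- medianOfRatios(counts)
  z <- sweep(counts, 2, size_factors, "/")
  mu <- rowMeans(z)
  if (is.null(groups)) {
    s2 <- apply(z, 1, stats::var)
  } else {
    groups <- as.factor(groups)
    if (any(table(groups) < 2L))
      stop("every group needs at least 2 samples for dispersion estimation",
           call. = FALSE)
    ss <- 0; df <- 0
    for (g in levels(groups)) {
      zg <- z[, groups == g, drop = FALSE]
      ss <- ss + rowSums((zg - rowMeans(zg))^2)
      df <- df + ncol(zg) - 1L
    }
    s2 <- ss / df
  }
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  # trend: mean raw dispersion within quantile bins of log mean expression
  ok <- mu > 0
  shrunk <- raw
  if (sum(ok) >= 2L && shrinkage > 0) {
    lm_ <- log(mu[ok])
    brk <- unique(stats::quantile(lm_, probs = seq(0, 1,
                                                   length.out = n_bins + 1)))
    bin <- cut(lm_, breaks = brk, include.lowest = TRUE)
    trend <- stats::ave(raw[ok], bin, FUN = mean)
    shrunk[ok] <- (1 - shrinkage) * raw[ok] + shrinkage * trend
  }
  stats::setNames(pmax(floor, shrunk), rownames(counts))
}

#' Two-group negative-binomial Wald contrast
#'
#' Simplified NB generalized linear model with log link for a single
#' two-group contrast: the per-group mean parameter is estimated as the
#' size-factor-weighted normalized mean (\code{sum(counts) / sum(size
#' factors)} within the group), the log2 fold change is the log2 ratio of
#' the treated over the reference group mean, and its standard error comes
#' from the NB Fisher information (\code{var = mu + alpha * mu^2}) by the
#' delta method. The Wald statistic (estimate / SE) is referred to a
#' standard normal, two-sided. When a group mean is exactly zero a
#' pseudo-count (default 0.5 reads) is added to that group only, keeping
#' the fold change finite; such features are flagged.
#'
#' Raw p-values are accompanied by Benjamini-Hochberg adjusted values.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param size_factors per-sample size factors.
#' @param dispersions per-feature NB dispersions (scalar recycled).
#' @param groups group labels, length = samples.
#' @param contrast character pair \code{c(treated, reference)}.
#' @param pseudo pseudo-count applied to zero group sums.
#' @return data.frame: \code{feature_id}, \code{mean_expr} (normalized mean
#'   over the two groups), \code{log2fc}, \code{se}, \code{stat}, \code{p},
#'   \code{padj}, \code{zero_group}.
#' @export
nbWaldContrast <- function(counts, size_factors, dispersions, groups,
                           contrast, pseudo = 0.5) {
  counts <- .asCountMatrix(counts)
  groups <- as.character(groups)
  stopifnot(length(contrast) == 2L)
  for (g in contrast)
    if (sum(groups == g) < 2L)
      stop("contrast group '", g, "' absent or has fewer than 2 samples",
           call. = FALSE)
  alpha <- rep(dispersions, length.out = nrow(counts))

  groupFit <- function(g) {
    j <- which(groups == g)
    s <- size_factors[j]
    k <- rowSums(counts[, j, drop = FALSE])
    q <- k / sum(s)
    zero <- q == 0
    q_adj <- (k + pseudo * zero) / sum(s)
    # delta-method variance of log(q_hat): sum(mu_j + alpha mu_j^2) /
    # (q sum s)^2 with mu_j = s_j q
    v <- (sum(s) + alpha * q_adj * sum(s^2)) / (q_adj * sum(s)^2)
    list(q = q_adj, v = v, zero = zero, k = k, s_sum = sum(s))
  }
  t_ <- groupFit(contrast[1])
  r_ <- groupFit(contrast[2])

  log2fc <- log2(t_$q / r_$q)
  se <- sqrt(t_$v + r_$v) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(
    feature_id = rownames(counts),
    mean_expr = (t_$k + r_$k) / (t_$s_sum + r_$s_sum),
    log2fc = log2fc, se = se, stat = stat, p = p,
    padj = bhAdjust(p),
    zero_group = t_$zero | r_$zero,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (with the cumulative-minimum
#' enforcement), order-preserving in the input. Thin validated wrapper
#' around \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Two-sample test cascade with normality and variance gating
#'
#' The classical decision cascade: both samples are tested for normality
#' (Shapiro-Wilk at \code{alpha}); if both pass, variances are compared by
#' the Levene test (classic, mean-centred) and the groups by Student's t
#' (equal variances) or Welch's t (unequal); if either sample is
#' non-normal, the Mann-Whitney test is used (Wilcoxon signed-rank when
#' paired). Every decision is recorded in a trace.
#'
#' @param sample_a,sample_b numeric vectors (n >= 3 each).
#' @param paired logical; paired design.
#' @param alpha gating and significance level.
#' @return list: \code{groups} (per-sample n / mean / sd / normality_p),
#'   \code{chosen_test} (\code{"t"}, \code{"welch"} or
#'   \code{"mann_whitney"}), \code{test_p}, \code{levene_p} (NA when not
#'   reached), \code{significant}, \code{trace}.
#' @export
statsCascade <- function(sample_a, sample_b, paired = FALSE, alpha = 0.05) {
  if (length(sample_a) < 3L || length(sample_b) < 3L)
    stop("need at least 3 observations per sample", call. = FALSE)
  if (paired && length(sample_a) != length(sample_b))
    stop("paired samples must have equal length", call. = FALSE)
  trace <- character()
  sw_a <- stats::shapiro.test(sample_a)$p.value
  sw_b <- stats::shapiro.test(sample_b)$p.value
  normal <- sw_a > alpha && sw_b > alpha
  trace <- c(trace, sprintf(
    "shapiro-wilk: p_a=%.4g, p_b=%.4g -> %s", sw_a, sw_b,
    if (normal) "normal" else "non-normal"))

  levene_p <- NA_real_
  if (normal) {
    if (paired) {
      chosen <- "t"
      ht <- stats::t.test(sample_a, sample_b, paired = TRUE)
      trace <- c(trace, "paired design: paired Student t")
    } else {
      lev <- car::leveneTest(
        c(sample_a, sample_b),
        factor(rep(c("a", "b"), c(length(sample_a), length(sample_b)))),
        center = mean)
      levene_p <- lev[["Pr(>F)"]][1]
      if (levene_p > alpha) {
        chosen <- "t"
        ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
        trace <- c(trace, sprintf(
          "levene: p=%.4g -> equal variances, Student t", levene_p))
      } else {
        chosen <- "welch"
        ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
        trace <- c(trace, sprintf(
          "levene: p=%.4g -> unequal variances, Welch t", levene_p))
      }
    }
  } else {
    chosen <- "mann_whitney"
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, paired = paired))
    trace <- c(trace, if (paired) "non-normal, paired: Wilcoxon signed-rank"
               else "non-normal: Mann-Whitney")
  }
  groups <- data.frame(
    group = c("a", "b"),
    n = c(length(sample_a), length(sample_b)),
    mean = c(mean(sample_a), mean(sample_b)),
    sd = c(stats::sd(sample_a), stats::sd(sample_b)),
    normality_p = c(sw_a, sw_b), stringsAsFactors = FALSE)
  list(groups = groups, chosen_test = chosen, test_p = ht$p.value,
       levene_p = levene_p, significant = ht$p.value <= alpha,
       trace = trace)
}

#' One-way ANOVA with Student-Newman-Keuls post hoc comparisons
#'
#' One-way ANOVA over three or more groups; when the ANOVA rejects at
#' \code{alpha}, the Student-Newman-Keuls stepwise range procedure is run
#' on the ordered group means: the range spanning r ordered means is
#' compared against the studentized-range critical value
#' \code{qtukey(1 - alpha, r, df_error)}, largest ranges first, and
#' sub-ranges of a non-significant range are declared non-significant
#' without testing. Unequal group sizes are handled with the
#' Tukey-Kramer standard error.
#'
#' @param groups named list of numeric vectors (>= 3 groups, n >= 2 each).
#' @param alpha significance level.
#' @return list: \code{anova_p}, \code{significant} (logical group x group
#'   matrix; all FALSE when the ANOVA does not reject), \code{means},
#'   \code{df_error}, \code{mse}.
#' @export
anovaSnk <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need at least 3 groups; use statsCascade() for two",
         call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  anova_p <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]

  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  if (anova_p <= alpha) {
    ord <- order(means)
    om <- means[ord]; on_ <- ns[ord]
    # stepwise: test range (lo, hi); recurse into sub-ranges only if
    # significant
    testRange <- function(lo, hi) {
      if (hi - lo < 1L) return()
      r <- hi - lo + 1L
      se <- sqrt(mse / 2 * (1 / on_[lo] + 1 / on_[hi]))
      q_obs <- (om[hi] - om[lo]) / se
      if (q_obs > stats::qtukey(1 - alpha, r, df_err)) {
        i <- names(om)[lo]; j <- names(om)[hi]
        sig[i, j] <<- TRUE; sig[j, i] <<- TRUE
        testRange(lo, hi - 1L)
        testRange(lo + 1L, hi)
      }
    }
    testRange(1L, k)
  }
  list(anova_p = anova_p, significant = sig, means = means,
       df_error = df_err, mse = mse)
}

#' Double-delta-Ct relative quantification
#'
#' Per-sample delta Ct (target minus housekeeping), per-group mean delta
#' Ct, delta-delta Ct vs the reference group, and fold change
#' \code{2^(-ddCt)}.
#'
#' @param ct numeric matrix of threshold cycles, features x samples.
#' @param housekeeping_id row name of the housekeeping feature (must be
#'   present and complete).
#' @param sample_groups group label per sample (column).
#' @param reference_group group the fold changes are relative to.
#' @return data.frame: \code{feature_id}, one fold-change column per group
#'   (reference included, identically 1).
#' @export
ddctFoldChange <- function(ct, housekeeping_id, sample_groups,
                           reference_group) {
  ct <- as.matrix(ct)
  if (!housekeeping_id %in% rownames(ct))
    stop("housekeeping feature '", housekeeping_id, "' missing",
         call. = FALSE)
  if (anyNA(ct[housekeeping_id, ]))
    stop("missing housekeeping Ct values", call. = FALSE)
  sample_groups <- as.character(sample_groups)
  if (!reference_group %in% sample_groups)
    stop("reference group absent from samples", call. = FALSE)
  dct <- sweep(ct, 2, ct[housekeeping_id, ], "-")
  dct <- dct[setdiff(rownames(ct), housekeeping_id), , drop = FALSE]
  grps <- unique(sample_groups)
  ref_mean <- rowMeans(dct[, sample_groups == reference_group,
                           drop = FALSE])
  out <- data.frame(feature_id = rownames(dct), stringsAsFactors = FALSE)
  for (g in grps) {
    ddct <- rowMeans(dct[, sample_groups == g, drop = FALSE]) - ref_mean
    out[[g]] <- 2^(-ddct)
  }
  out
}
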