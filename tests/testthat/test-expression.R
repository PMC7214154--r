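test_that("median-of-ratios handles forced cases and planted libraries", {
  m <- matrix(rpois(50 * 4, 60), 50, 4,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  expect_equal(unname(medianOfRatios(cbind(m[, 1], m[, 1], m[, 1]))),
               rep(1, 3))
  two <- cbind(A = m[, 1] + 1, B = 2 * (m[, 1] + 1))
  expect_equal(unname(medianOfRatios(two)), c(1 / sqrt(2), sqrt(2)))
  # planted 4-fold library-size span: estimated ratios within 10% of truth
  se <- simulateMirCounts(simConfig(seed = 21, n_mirs = 300, n_de = 30,
                                    n_up = 10, n_down = 10))
  sf <- medianOfRatios(SummarizedExperiment::assay(se))
  truth <- se$true_size_factor
  gm <- function(x) exp(mean(log(x)))
  ratio <- (sf / gm(sf)) / (truth / gm(truth))
  expect_true(all(abs(ratio - 1) < 0.1))
  # all-zero-containing reference set is an explicit error
  z <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(medianOfRatios(z), "pseudo-reference")
})

test_that("median-of-ratios agrees with the established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  mu <- matrix(rnbinom(200 * 6, mu = 80, size = 5), 200, 6)
  libs <- c(1, 1.5, 2, 0.7, 1.2, 0.9)
  m <- matrix(rpois(length(mu), sweep(mu, 2, libs, "*")), 200, 6)
  # the reference takes the median on the log scale; with an even feature
  # count the two middle ratios are averaged geometrically there vs
  # arithmetically here, so agreement is to ~1e-4, not machine precision
  expect_equal(unname(medianOfRatios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-4)
})

test_that("dispersion estimates behave across regimes", {
  set.seed(5)
  # Poisson counts at large means: shrunk dispersion near zero
  mp <- matrix(rpois(400 * 20, 500), 400, 20)
  expect_lt(median(estimateDispersion(mp, rep(1, 20))), 0.01)
  # NB alpha = 0.2 at n = 20: median estimate in a sane window
  meds <- vapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(rnbinom(300 * 20, mu = 200, size = 1 / 0.2), 300, 20)
    median(estimateDispersion(m, rep(1, 20)))
  }, numeric(1))
  expect_true(all(meds > 0.1 & meds < 0.4))
  # constant feature floored
  mc <- rbind(rep(50, 10), matrix(rpois(90 * 10, 50), 90, 10))
  expect_equal(unname(estimateDispersion(mc, rep(1, 10),
                                         shrinkage = 0)[1]), 1e-8)
  expect_error(estimateDispersion(mp, rep(1, 20),
                                  groups = c("a", rep("b", 19))),
               "at least 2")
})

test_that("NB Wald contrast is exact on degenerate input and antisymmetric", {
  set.seed(8)
  m <- matrix(rnbinom(100 * 10, mu = 50, size = 10), 100, 10,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:10)))
  g <- rep(c("T", "R"), each = 5)
  sf <- rep(1, 10)
  # identical counts in both groups: log2fc identically zero
  mm <- cbind(m[, 1:5], m[, 1:5])
  r0 <- nbWaldContrast(mm, sf, 0.1, g, c("T", "R"))
  expect_true(all(r0$log2fc == 0))
  # swapping the contrast negates log2fc and preserves p
  a <- nbWaldContrast(m, sf, 0.1, g, c("T", "R"))
  b <- nbWaldContrast(m, sf, 0.1, g, c("R", "T"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_true(all(a$padj >= a$p))
  expect_error(nbWaldContrast(m, sf, 0.1, g, c("T", "X")), "absent")
})

test_that("NB Wald estimate and SE match a fixed-theta GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(12)
  alpha <- 0.15
  m <- matrix(rnbinom(20 * 12, mu = 70, size = 1 / alpha), 20, 12,
              dimnames = list(paste0("f", 1:20), NULL))
  g <- factor(rep(c("R", "T"), each = 6), levels = c("R", "T"))
  ours <- nbWaldContrast(m, rep(1, 12), alpha, as.character(g),
                         c("T", "R"))
  for (i in 1:20) {
    fit <- stats::glm(m[i, ] ~ g,
                      family = MASS::negative.binomial(theta = 1 / alpha))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(ours$log2fc[i], co["gT", "Estimate"] / log(2),
                 tolerance = 1e-6)
    expect_equal(ours$se[i], co["gT", "Std. Error"] / log(2),
                 tolerance = 1e-4)
  }
})

test_that("planted effects are recovered and the null is calibrated", {
  # parameter recovery: planted log2FC = 1 at n = 20/group, alpha = 0.1
  ests <- vapply(1:3, function(s) {
    set.seed(s)
    mu0 <- rlnorm(200, 5, 1)
    m <- cbind(
      matrix(rnbinom(200 * 20, mu = rep(mu0 * 2, 20), size = 10), 200, 20),
      matrix(rnbinom(200 * 20, mu = rep(mu0, 20), size = 10), 200, 20))
    rownames(m) <- paste0("f", 1:200)
    g <- rep(c("T", "R"), each = 20)
    mean(nbWaldContrast(m, rep(1, 40), 0.1, g, c("T", "R"))$log2fc)
  }, numeric(1))
  expect_true(all(abs(ests - 1) < 0.1))
  # type-I error at the null in [0.03, 0.07]
  set.seed(99)
  mu0 <- rlnorm(2000, 5, 1)
  m <- matrix(rnbinom(2000 * 40, mu = rep(mu0, 40), size = 10), 2000, 40)
  rownames(m) <- paste0("f", 1:2000)
  g <- rep(c("T", "R"), each = 20)
  disp <- estimateDispersion(m, rep(1, 40), groups = g)
  rej <- mean(nbWaldContrast(m, rep(1, 40), disp, g, c("T", "R"))$p <= 0.05)
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("BH adjustment matches the definition oracle", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:80, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, bhOracle(p))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the test cascade picks the prescribed branch", {
  set.seed(10)
  x <- rnorm(20)
  same <- statsCascade(x, rev(x))   # identical samples: t branch, p = 1
  expect_equal(same$chosen_test, "t")
  expect_gt(same$test_p, 0.9)
  # 25-fold variance ratio routes to Welch in nearly all seeds
  welch <- vapply(1:10, function(s) {
    set.seed(s)
    statsCascade(rnorm(20, 0, 1), rnorm(20, 0, 5))$chosen_test
  }, character(1))
  expect_gte(sum(welch == "welch"), 9)
  # heavy-tailed contamination routes to Mann-Whitney in most seeds
  mw <- vapply(1:10, function(s) {
    set.seed(s)
    a <- c(rnorm(16), rcauchy(4) * 10)
    statsCascade(a, rnorm(20))$chosen_test
  }, character(1))
  expect_gte(sum(mw == "mann_whitney"), 8)
  expect_error(statsCascade(1:2, 1:5), "at least 3")
})

test_that("ANOVA + SNK flags exactly the shifted group", {
  set.seed(3)
  base <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  res0 <- anovaSnk(lapply(base, function(x) x - mean(x)))
  expect_false(any(res0$significant))
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 5)
    res <- anovaSnk(g)
    res$significant["a", "c"] && res$significant["b", "c"] &&
      !res$significant["a", "b"]
  }, logical(1))
  expect_gte(sum(hits), 9)
  expect_error(anovaSnk(list(a = 1:5, b = 1:5)), "at least 3")
})

test_that("SNK decisions equal a hand-computed studentized-range oracle", {
  g <- list(g1 = c(1.2, 0.8, 1.1, 0.9, 1.0),
            g2 = c(1.9, 2.2, 2.0, 2.1, 1.8),
            g3 = c(4.1, 3.8, 4.0, 4.2, 3.9))
  res <- anovaSnk(g, alpha = 0.05)
  # manual computation: MSE and df from one-way ANOVA identities
  n <- 5; k <- 3
  means <- vapply(g, mean, numeric(1))
  mse <- mean(vapply(g, var, numeric(1)))
  df <- k * (n - 1)
  seh <- sqrt(mse / n)
  dec <- function(m1, m2, r)
    unname((abs(m1 - m2) / seh) > qtukey(0.95, r, df))
  expect_equal(res$mse, mse, tolerance = 1e-12)
  expect_equal(unname(res$significant["g1", "g3"]),
               dec(means[1], means[3], 3))
  expect_equal(unname(res$significant["g1", "g2"]),
               dec(means[1], means[2], 2))
  expect_equal(unname(res$significant["g2", "g3"]),
               dec(means[2], means[3], 2))
})

test_that("ddCt fold change equals independent spreadsheet arithmetic", {
  set.seed(6)
  ct <- matrix(runif(4 * 6, 18, 30), 4, 6,
               dimnames = list(c("g1", "g2", "g3", "hk"), paste0("s", 1:6)))
  grp <- rep(c("ref", "trt"), each = 3)
  f <- ddctFoldChange(ct, "hk", grp, "ref")
  for (gene in c("g1", "g2", "g3")) {
    d <- ct[gene, ] - ct["hk", ]
    ddct <- mean(d[4:6]) - mean(d[1:3])
    expect_equal(f$trt[f$feature_id == gene], 2^(-ddct),
                 tolerance = 1e-12)
    expect_equal(f$ref[f$feature_id == gene], 1, tolerance = 1e-12)
  }
})
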