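# NB Wald differential abundance: normalization, dispersion estimation,
# Wald tests and direction classification.

simulate_nb_counts <- function(n, m, dispersion, mu_range = c(20, 2000),
                               seed = 1, sf = rep(1, n)) {
  set.seed(seed)
  mu <- exp(runif(m, log(mu_range[1]), log(mu_range[2])))
  counts <- sapply(seq_len(m), function(j) {
    mm <- mu[j] * sf
    if (dispersion == 0) rpois(n, mm)
    else rnbinom(n, size = 1 / dispersion, mu = mm)
  })
  dimnames(counts) <- list(sprintf("S%03d", 1:n), sprintf("k__B|s__t%03d", 1:m))
  counts
}

test_that("size factors implement median-of-ratios with geometric-mean-1 scaling", {
  m <- rbind(S1 = c(10, 40, 100), S2 = c(10, 40, 100))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- rbind(S1 = c(10, 40, 100), S2 = 3 * c(10, 40, 100))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(3), sqrt(3)))
  expect_equal(size_factors(m2 * 10), size_factors(m2))       # ratio invariance
  m3 <- rbind(S1 = c(0, 40), S2 = c(10, 0))                   # no all-nonzero taxon
  expect_warning(sf3 <- size_factors(m3), "falling back")
  expect_true(all(is.finite(sf3) & sf3 > 0))
})

test_that("NB fit reduces to the Poisson GLM in the zero-dispersion limit", {
  counts <- simulate_nb_counts(60, 1, dispersion = 0, seed = 5)
  x <- rep(c(0, 1), 30)
  sf <- exp(rnorm(60, 0, 0.2))
  X <- cbind(intercept = 1, x = x)
  fit <- nb_glm_fit(counts[, 1], X, offset = log(sf), dispersion = 0)
  oracle <- glm(counts[, 1] ~ x + offset(log(sf)), family = poisson())
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(oracle)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("dispersion estimation recovers simulated values", {
  X <- cbind(1, rep(c(0, 1), 50))
  counts <- simulate_nb_counts(100, 200, dispersion = 0.2, seed = 7)
  disp <- estimate_dispersions(counts, X, sf = rep(1, 100))
  expect_gt(median(disp$alpha_map), 0.15)
  expect_lt(median(disp$alpha_map), 0.27)
  pois <- simulate_nb_counts(100, 120, dispersion = 0, seed = 8)
  disp0 <- estimate_dispersions(pois, X, sf = rep(1, 100))
  expect_lt(median(disp0$alpha_map), 0.05)
  # constant counts across samples: no overdispersion, lower bound
  const <- cbind(counts[, 1:10], const = rep(50, 100))
  colnames(const)[11] <- "k__B|s__const"
  dc <- estimate_dispersions(const, X, sf = rep(1, 100))
  expect_lt(dc$alpha_mle[["k__B|s__const"]], 1e-6)
})

test_that("Wald results satisfy their structural contract", {
  counts <- simulate_nb_counts(80, 50, dispersion = 0.3, seed = 9)
  cond <- rep(c(FALSE, TRUE), 40)
  res <- wald_test(counts, cond)
  expect_s3_class(res, "da_result")
  ok <- res$converged
  expect_gt(mean(ok), 0.9)
  expect_equal(res$wald_stat[ok], (res$log2_fc / res$se)[ok], tolerance = 1e-8)
  expect_true(all(res$p_adjusted[ok] >= res$p_value[ok] - 1e-12))
  expect_error(wald_test(counts, rep(TRUE, 80)), "2 levels")
})

test_that("recoding the condition flips every log2 fold change", {
  counts <- simulate_nb_counts(60, 40, dispersion = 0.25, seed = 10)
  cond <- factor(rep(c("ctrl", "case"), 30), levels = c("ctrl", "case"))
  a <- wald_test(counts, cond)
  b <- wald_test(counts, factor(cond, levels = c("case", "ctrl")))
  ok <- a$converged & b$converged
  expect_equal(a$log2_fc[ok], -b$log2_fc[ok], tolerance = 1e-6)
})

test_that("a common count multiple is absorbed by the size factors", {
  counts <- simulate_nb_counts(60, 40, dispersion = 0.25, seed = 11)
  cond <- rep(c(FALSE, TRUE), 30)
  # size factors themselves are exactly scale-free
  expect_equal(size_factors(counts * 7), size_factors(counts), tolerance = 1e-12)
  # with equal size factors the group MLE is the group mean, exactly scale-free
  even <- matrix(rep(counts[, 1], 2), ncol = 2,
                 dimnames = list(rownames(counts), c("k__B|s__a", "k__B|s__b")))
  X <- cbind(1, cond)
  f1 <- nb_glm_fit(even[, 1], X, offset = rep(0, 60), dispersion = 0.25)
  f7 <- nb_glm_fit(even[, 1] * 7, X, offset = rep(0, 60), dispersion = 0.25 / 7)
  expect_equal(f1$beta[[2]], f7$beta[[2]], tolerance = 1e-8)
  # on the full path, dispersion re-estimation keeps a weak shot-noise
  # dependence on the absolute scale, so fold changes agree approximately
  a <- wald_test(counts, cond)
  b <- wald_test(counts * 7, cond)
  ok <- a$converged & b$converged
  expect_equal(a$log2_fc[ok], b$log2_fc[ok], tolerance = 0.02)
})

test_that("direction classification applies the significance rule", {
  res <- data.frame(taxon = c("t1", "t2", "t3"),
                    log2_fc = c(1.2, -0.8, 2.0),
                    p_adjusted = c(0.01, 0.03, 0.20))
  sets <- classify_directions(res, alpha = 0.05)
  expect_identical(sets$increased, "t1")
  expect_identical(sets$decreased, "t2")
  empty <- classify_directions(transform(res, p_adjusted = 0.9))
  expect_length(empty$increased, 0)
  expect_length(empty$decreased, 0)
})

test_that("Wald machinery agrees with DESeq2 at matched normalization and dispersion", {
  skip_if_not_installed("DESeq2")
  n <- 50; m <- 30
  counts <- simulate_nb_counts(n, m, dispersion = 0.2, seed = 13)
  cond <- factor(rep(c("ctrl", "case"), n / 2), levels = c("ctrl", "case"))
  smoking <- factor(sample(c("never", "former", "current"), n, TRUE),
                    levels = c("never", "former", "current"))
  suppressPackageStartupMessages(library(DESeq2))
  dds <- DESeqDataSetFromMatrix(t(counts), data.frame(cond = cond, smoking = smoking),
                                ~ smoking + cond)
  sf <- size_factors(counts)
  sizeFactors(dds) <- sf
  dispersions(dds) <- rep(0.2, m)
  dds <- nbinomWaldTest(dds, betaPrior = FALSE)
  ref <- results(dds, name = "cond_case_vs_ctrl")
  X <- model.matrix(~ smoking + cond)
  fits <- lapply(seq_len(m), function(j)
    nb_glm_fit(counts[, j], X, offset = log(sf), dispersion = 0.2))
  mine_lfc <- vapply(fits, function(f) unname(f$beta["condcase"]) / log(2), numeric(1))
  mine_se <- vapply(fits, function(f) unname(f$se["condcase"]) / log(2), numeric(1))
  expect_equal(mine_lfc, ref$log2FoldChange, tolerance = 1e-4)
  expect_equal(mine_se, ref$lfcSE, tolerance = 1e-3)
})
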