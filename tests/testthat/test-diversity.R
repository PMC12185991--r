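# Alpha diversity, Bray-Curtis, PCoA and PERMANOVA.

test_that("shannon index matches direct formula evaluation", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon(p), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "zero total")
})

test_that("inverse Simpson matches direct formula evaluation", {
  for (k in c(2, 5, 9)) expect_equal(inverse_simpson(rep(3, k)), k)
  expect_equal(inverse_simpson(c(0, 4)), 1)
  expect_equal(inverse_simpson(c(0.5, 0.5)), 2)
})

test_that("diversity indices are invariant to positive rescaling", {
  set.seed(2)
  v <- rexp(20)
  for (k in c(0.01, 3, 1000)) {
    expect_equal(shannon(v * k), shannon(v), tolerance = 1e-12)
    expect_equal(inverse_simpson(v * k), inverse_simpson(v), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis dissimilarities follow the defining ratio", {
  vals <- rbind(A = c(2, 0), B = c(1, 1), C = c(2, 0), D = c(0, 5))
  colnames(vals) <- c("k__B|s__x", "k__B|s__y")
  d <- as.matrix(bray_curtis_matrix(abundance_table(vals, "species")))
  expect_equal(d["A", "C"], 0)            # identical samples
  expect_equal(d["A", "D"], 1)            # disjoint supports
  expect_equal(d["A", "B"], 0.5)          # (|2-1| + |0-1|) / (3 + 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  zero <- rbind(A = c(1, 1), B = c(0, 0))
  colnames(zero) <- colnames(vals)
  expect_error(bray_curtis_matrix(abundance_table(zero, "species")), "B")
})

test_that("PCoA reproduces classical-scaling geometry", {
  # three collinear points at distances (1, 1, 2)
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- pcoa(as.dist(d), n_axes = 2)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1)
  ax1 <- sort(ord$coordinates[, 1])
  expect_equal(unname(ax1), c(-1, 0, 1), tolerance = 1e-8)
  # two samples sit at +/- d/2 on a single axis
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoa(as.dist(d2), n_axes = 1)
  expect_equal(sort(unname(ord2$coordinates[, 1])), c(-1.5, 1.5))
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
})

test_that("PCoA on Euclidean distances recovers the point configuration", {
  set.seed(7)
  pts <- matrix(rnorm(24 * 2), 24, 2)
  rownames(pts) <- sprintf("S%02d", 1:24)
  ord <- pcoa(dist(pts), n_axes = 2)
  pr <- vegan::procrustes(pts, ord$coordinates, symmetric = FALSE)
  expect_lt(pr$ss, 1e-8)   # residual after optimal rotation/translation
})

make_blocked_dist <- function() {
  set.seed(31)
  g1 <- matrix(rnorm(10 * 3, 0), 10, 3)
  g2 <- matrix(rnorm(10 * 3, 8), 10, 3)
  pts <- rbind(g1, g2)
  rownames(pts) <- sprintf("S%02d", 1:20)
  list(d = dist(pts), group = rep(c("a", "b"), each = 10))
}

test_that("PERMANOVA attains the minimal p under clear separation", {
  bl <- make_blocked_dist()
  res <- permanova(bl$d, bl$group, n_perm = 999, seed = 4)
  grp <- res[res$term == "group", ]
  expect_equal(grp$p_value, 1 / (999 + 1))
  expect_gt(grp$R2, 0.9)
})

test_that("PERMANOVA sums of squares partition the total", {
  set.seed(12)
  pts <- matrix(rnorm(30 * 4), 30, 4)
  d <- dist(pts)
  cov <- data.frame(age = rnorm(30), smoking = sample(c("n", "f", "c"), 30, TRUE))
  res <- permanova(d, sample(c("x", "y"), 30, TRUE), covariates = cov,
                   n_perm = 199, seed = 2)
  total <- res$sum_sq[res$term == "Total"]
  expect_equal(sum(res$sum_sq[res$term != "Total"]), total, tolerance = 1e-8)
  expect_equal(sum(res$R2[res$term != "Total"]), 1, tolerance = 1e-8)
})

test_that("PERMANOVA statistics are invariant to sample reordering", {
  bl <- make_blocked_dist()
  res <- permanova(bl$d, bl$group, n_perm = 199, seed = 9)
  perm <- sample(20)
  d2 <- as.dist(as.matrix(bl$d)[perm, perm])
  res2 <- permanova(d2, bl$group[perm], n_perm = 199, seed = 9)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-10)
  expect_equal(res2$R2, res$R2, tolerance = 1e-10)
})

test_that("degenerate groupings are rejected or uninformative", {
  bl <- make_blocked_dist()
  expect_error(permanova(bl$d, rep("a", 20)), "constant")
  # two identical blocks with group = block: no separation
  m <- as.matrix(bl$d)
  res <- permanova(as.dist(m), rep(c("u", "v"), 10), n_perm = 199, seed = 1)
  expect_lt(res$R2[res$term == "group"], 0.1)
  expect_true(is.finite(res$pseudo_F[res$term == "group"]))
})
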