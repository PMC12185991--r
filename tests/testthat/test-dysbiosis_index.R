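# Mann-Whitney machinery, sensitivity pruning and the log10 ratio index.

test_that("exact Mann-Whitney matches hand enumeration", {
  res <- mwu_test(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  same <- mwu_test(c(1, 2, 2, 5), c(2, 5, 1, 2))
  expect_equal(same$p_value, 1)
  expect_error(mwu_test(numeric(0), 1), "non-empty")
})

test_that("exact enumeration agrees with the brute-force oracle for all small splits", {
  set.seed(14)
  pools <- list(rnorm(8),                       # continuous, no ties
                sample(1:4, 8, TRUE),           # heavy ties
                c(rep(1, 5), rnorm(3)))         # mixed
  for (pool in pools) {
    for (nx in 1:7) {
      x <- pool[seq_len(nx)]
      y <- pool[-seq_len(nx)]
      got <- mwu_test(x, y)
      want <- mwu_oracle(x, y)
      expect_equal(got$u_statistic, want$u, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
      expect_lte(got$u_statistic, nx * (8 - nx))
    }
  }
})

test_that("large-sample path matches the tie-corrected normal reference", {
  set.seed(15)
  x <- round(rnorm(25, 0, 2), 1)
  y <- round(rnorm(30, 0.5, 2), 1)
  got <- mwu_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_identical(got$method, "normal")
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("null Mann-Whitney p-values are calibrated", {
  set.seed(16)
  p <- replicate(500, mwu_test(rnorm(20), rnorm(20))$p_value)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

make_prune_fixture <- function() {
  n <- 40
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  set.seed(17)
  vals <- cbind(
    strong_up = ifelse(grp, 8, 2) + runif(n, 0, 0.5),   # clearly separated
    flat = c(seq_len(n / 2), seq_len(n / 2)) / 10,      # identical multisets
    strong_dn = ifelse(grp, 1, 6) + runif(n, 0, 0.5))
  colnames(vals) <- paste0("k__B|s__", colnames(vals))
  rownames(vals) <- sprintf("S%02d", seq_len(n))
  list(tab = abundance_table(vals, "species"), grp = grp)
}

test_that("pruning removes exactly the taxa failing the Mann-Whitney rule", {
  fx <- make_prune_fixture()
  sets <- structure(list(increased = c("k__B|s__strong_up", "k__B|s__flat"),
                         decreased = "k__B|s__strong_dn", alpha = 0.05),
                    class = "direction_sets")
  pruned <- prune_sets(fx$tab, fx$grp, sets, p_threshold = 0.10)
  expect_identical(pruned$increased, "k__B|s__strong_up")
  expect_identical(pruned$decreased, "k__B|s__strong_dn")
  p <- attr(pruned, "prune_p")
  expect_gt(p[["k__B|s__flat"]], 0.10)
  # taxa exactly at the threshold are retained; threshold 1 is a no-op
  noop <- prune_sets(fx$tab, fx$grp, sets, p_threshold = 1)
  expect_identical(noop$increased, sets$increased)
  expect_identical(noop$decreased, sets$decreased)
  # missing outcomes are ignored rather than propagated
  grp_na <- fx$grp
  grp_na[1:3] <- NA
  expect_silent(prune_sets(fx$tab, grp_na, sets))
})

test_that("the index is the log10 ratio of set sums with a pseudocount", {
  vals <- rbind(S1 = c(5, 5, 2, 8),      # balanced: sum inc = sum dec
                S2 = c(40, 10, 4, 1),    # inc = 10 x dec
                S3 = c(3, 1, 0, 0))      # zero denominator
  colnames(vals) <- paste0("k__B|s__t", 1:4)
  tab <- abundance_table(vals, "species")
  sets <- structure(list(increased = c("k__B|s__t1", "k__B|s__t2"),
                         decreased = c("k__B|s__t3", "k__B|s__t4"), alpha = 0.05),
                    class = "direction_sets")
  idx <- dysbiosis_index(tab, sets, pseudocount = 1e-6)
  expect_equal(unname(idx["S1"]), 0)
  expect_equal(unname(idx["S2"]), 1, tolerance = 1e-6)
  expect_equal(unname(idx["S3"]), log10((4 + 1e-6) / 1e-6))
  expect_true(all(is.finite(idx)))
  # default pseudocount: half the smallest nonzero abundance
  idx_def <- dysbiosis_index(tab, sets)
  expect_equal(attr(idx_def, "pseudocount"), 0.5)
  expect_equal(unname(idx_def["S3"]), log10(4.5 / 0.5))
})

test_that("the index is antisymmetric and scale invariant", {
  set.seed(18)
  vals <- matrix(rexp(60), 10, 6,
                 dimnames = list(sprintf("S%02d", 1:10),
                                 paste0("k__B|s__t", 1:6)))
  vals[3, 1:2] <- 0
  tab <- abundance_table(vals, "species")
  sets <- structure(list(increased = paste0("k__B|s__t", 1:3),
                         decreased = paste0("k__B|s__t", 4:6), alpha = 0.05),
                    class = "direction_sets")
  swapped <- structure(list(increased = sets$decreased,
                            decreased = sets$increased, alpha = 0.05),
                       class = "direction_sets")
  idx <- dysbiosis_index(tab, sets, pseudocount = 0.01)
  expect_equal(as.numeric(idx),
               -as.numeric(dysbiosis_index(tab, swapped, pseudocount = 0.01)),
               tolerance = 1e-14)
  scaled <- abundance_table(vals * 3, "species")
  expect_equal(as.numeric(dysbiosis_index(scaled, sets, pseudocount = 0.03)),
               as.numeric(idx), tolerance = 1e-12)
  empty <- structure(list(increased = character(), decreased = sets$decreased,
                          alpha = 0.05), class = "direction_sets")
  expect_error(dysbiosis_index(tab, empty), "undefined")
})

test_that("the index separates cases from controls on planted cohorts", {
  seps <- vapply(1:5, function(s) {
    co <- generate_cohort(sim_config(), seed = 300 + s)
    sets <- structure(list(increased = names(co$truth$enriched_taxa),
                           decreased = names(co$truth$depleted_taxa),
                           alpha = 0.05), class = "direction_sets")
    idx <- dysbiosis_index(co$abundance, sets)
    rapid <- co$metadata$rapid_decline
    ok <- !is.na(rapid)
    mwu_test(idx[ok & rapid], idx[ok & !rapid])$p_value
  }, numeric(1))
  expect_lt(median(seps), 0.01)
})
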