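# Alpha diversity, Bray-Curtis dissimilarity, principal coordinates and
# covariate-adjusted PERMANOVA.

#' Shannon diversity of one abundance vector
#'
#' `H = -sum(p_i * ln(p_i))` over nonzero proportions, with the input
#' normalized to proportions first (natural log), so the index is invariant
#' to rescaling by a positive constant.
#'
#' @param abund non-negative numeric vector with positive sum.
#' @return Shannon index (nats).
#' @export
shannon <- function(abund) {
  .check_abund(abund)
  as.numeric(vegan::diversity(matrix(abund, nrow = 1), index = "shannon"))
}

#' Inverse Simpson diversity of one abundance vector
#'
#' `1 / sum(p_i^2)` on normalized proportions.
#'
#' @inheritParams shannon
#' @return inverse Simpson index.
#' @export
inverse_simpson <- function(abund) {
  .check_abund(abund)
  as.numeric(vegan::diversity(matrix(abund, nrow = 1), index = "invsimpson"))
}

.check_abund <- function(abund) {
  if (!is.numeric(abund) || anyNA(abund) || any(abund < 0))
    stop("abundances must be non-negative and finite")
  if (sum(abund) <= 0) stop("abundance vector has zero total")
  invisible(TRUE)
}

#' Per-sample alpha diversity table
#'
#' @param table an [abundance_table()].
#' @return data.frame with `sample_id`, `shannon`, `inverse_simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  data.frame(sample_id = sample_ids(table),
             shannon = apply(table$values, 1, shannon),
             inverse_simpson = apply(table$values, 1, inverse_simpson),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare an alpha-diversity measure between two groups
#'
#' Mann-Whitney U comparison (see [mwu_test()]) of a per-sample diversity
#' value between the two outcome groups.
#'
#' @param values named per-sample numeric vector.
#' @param group logical or 2-level per-sample labels aligned with `values`.
#' @return an `mwu_result` (see [mwu_test()]).
#' @export
alpha_diversity_test <- function(values, group) {
  keep <- !is.na(group) & !is.na(values)
  g <- group[keep]
  lev <- unique(g)
  if (length(lev) != 2) stop("group must have exactly 2 levels")
  mwu_test(values[keep][g == lev[1]], values[keep][g == lev[2]])
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on the raw values; in
#' \[0, 1\], symmetric, zero diagonal.
#'
#' @param table an [abundance_table()].
#' @return A `dist` object labelled by sample ids.
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$values) < 2) stop("need >= 2 samples")
  zero <- rowSums(table$values) <= 0
  if (any(zero))
    stop("sample(s) with zero total abundance: ",
         paste(sample_ids(table)[zero], collapse = ", "))
  vegan::vegdist(table$values, method = "bray")
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Negative eigenvalues are retained in the eigenvalue list
#' but yield no coordinate axes; `proportion_explained` is computed over
#' the positive eigenvalues only.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param n_axes number of coordinate axes requested (trimmed to the
#'   number of positive eigenvalues).
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, all) and `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n_axes < 1 || n_axes > n - 1) n_axes <- min(max(n_axes, 1), n - 1)
  fit <- cmdscale(d, k = n_axes, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  k <- min(n_axes, length(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = pos / sum(pos))
}

#' Covariate-adjusted PERMANOVA
#'
#' Sequential (terms-in-order) partition of the Gower-centred total sum of
#' squares with covariates entered before the group term, pseudo-F per
#' term, and permutation p-values from free permutation of sample
#' identities (the behaviour of `vegan::adonis2` with `by = "terms"`,
#' which performs the computation). Deterministic given `seed`.
#'
#' @param d a `dist` of pairwise dissimilarities.
#' @param group per-sample labels for the term of interest (entered last).
#' @param covariates optional data.frame of per-sample adjustment
#'   covariates (entered first, in column order).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per term (plus Residual/Total):
#'   `term`, `df`, `sum_sq`, `R2`, `pseudo_F`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, group, covariates = NULL, n_perm = 999, seed = 1) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (length(group) != n) stop("`group` must align with the distance matrix")
  if (length(unique(group[!is.na(group)])) < 2)
    stop("`group` is constant; PERMANOVA undefined")
  if (n_perm < 99) stop("n_perm must be >= 99")
  df <- data.frame(group = factor(group))
  terms <- "group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must align with samples")
    df <- cbind(covariates, df)
    terms <- c(names(covariates), "group")
  }
  keep <- complete.cases(df)
  if (!all(keep)) {
    d <- as.dist(as.matrix(d)[keep, keep])
    df <- df[keep, , drop = FALSE]
  }
  set.seed(seed)
  frm <- reformulate(terms, response = quote(d))
  fit <- vegan::adonis2(frm, data = df, permutations = n_perm, by = "terms")
  data.frame(term = rownames(fit),
             df = fit$Df,
             sum_sq = fit$SumOfSqs,
             R2 = fit$R2,
             pseudo_F = fit$F,
             p_value = fit$`Pr(>F)`,
             n_permutations = n_perm,
             row.names = NULL, stringsAsFactors = FALSE)
}
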