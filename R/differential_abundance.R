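# Negative-binomial Wald differential abundance: median-of-ratios size
# factors, taxon-wise ML dispersions with a parametric (a0 + a1/mu) trend
# and posterior-mode shrinkage, then per-taxon Wald tests of a 2-level
# condition adjusted for covariates.

.LOG_ALPHA_LO <- log(1e-8)
.LOG_ALPHA_HI <- log(1e5)

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference taxa of `count / geometric mean
#' count`, where reference taxa are those with nonzero counts in every
#' sample; the factors are then normalized to geometric mean 1. When no
#' taxon is nonzero everywhere, geometric means are computed over positive
#' counts only (with a warning).
#'
#' @param counts a `count_table` (see [to_counts()]) or samples x taxa
#'   count matrix.
#' @return named per-sample positive size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (nrow(m) < 2) stop("need >= 2 samples")
  all_pos <- colSums(m > 0) == nrow(m)
  if (any(all_pos)) {
    ref <- m[, all_pos, drop = FALSE]
    loggeo <- colMeans(log(ref))
    sf <- apply(ref, 1, function(row) exp(median(log(row) - loggeo)))
  } else {
    warning("no taxon with nonzero counts in all samples; ",
            "falling back to positive-count geometric means")
    logm <- log(m)
    logm[!is.finite(logm)] <- NA
    loggeo <- colMeans(logm, na.rm = TRUE)
    sf <- apply(m, 1, function(row) {
      r <- log(row) - loggeo
      exp(median(r[is.finite(r)]))
    })
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, rownames(m))
}

# Parametric dispersion trend alpha(mu) = a0 + a1/mu, fitted by iterated
# gamma-family regression across taxa with outlier exclusion, as is
# conventional for mean-dispersion trends. Falls back to a flat trend at
# the median when the fit degenerates.
.fit_dispersion_trend <- function(alpha_mle, base_mean) {
  use <- is.finite(alpha_mle) & is.finite(base_mean) & base_mean > 0 &
    alpha_mle > exp(.LOG_ALPHA_LO) * 2 & alpha_mle < exp(.LOG_ALPHA_HI) / 2
  if (sum(use) < 10)
    return(list(a0 = median(alpha_mle[is.finite(alpha_mle)], na.rm = TRUE), a1 = 0))
  a <- alpha_mle[use]
  mu <- base_mean[use]
  coefs <- c(a0 = median(a), a1 = 0)
  for (iter in 1:3) {
    fit <- tryCatch(
      glm(a ~ I(1 / mu), family = Gamma(link = "identity"),
          start = pmax(coefs, c(1e-4, 0))),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) break
    coefs <- pmax(coef(fit), c(1e-6, 0))
    pred <- coefs[1] + coefs[2] / mu
    ratio <- a / pred
    keep <- ratio > 1e-4 & ratio < 15
    if (all(keep)) break
    a <- a[keep]
    mu <- mu[keep]
  }
  list(a0 = unname(coefs[1]), a1 = unname(coefs[2]))
}

#' Estimate per-taxon negative-binomial dispersions
#'
#' Three steps: (1) taxon-wise maximum-likelihood dispersion under an NB
#' GLM with log link and size-factor offsets; (2) a parametric trend
#' `alpha(mu) = a0 + a1/mu` fitted across taxa by gamma-family regression;
#' (3) final dispersions as the posterior mode shrinking the taxon-wise
#' estimate toward the trend under a normal prior on the log scale with
#' fixed variance `prior_var`.
#'
#' @param counts a `count_table` or samples x taxa count matrix.
#' @param design design matrix (samples x coefficients), full rank.
#' @param sf optional size factors (computed via [size_factors()] if NULL).
#' @param prior_var log-scale prior variance for the shrinkage (default
#'   0.25).
#' @return list with `alpha_mle`, `alpha_trend`, `alpha_map` (the final
#'   dispersions), `base_mean` and the trend coefficients.
#' @export
estimate_dispersions <- function(counts, design, sf = NULL, prior_var = 0.25) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  design <- as.matrix(design)
  if (nrow(m) <= ncol(design))
    stop("need more samples than design columns")
  if (qr(design)$rank < ncol(design)) stop("design matrix not full rank")
  if (is.null(sf)) sf <- size_factors(m)
  offset <- log(sf)
  base_mean <- colMeans(sweep(m, 1, sf, "/"))
  la_mle <- nb_ml_dispersions_cpp(m, design, offset, .LOG_ALPHA_LO, .LOG_ALPHA_HI)
  alpha_mle <- exp(la_mle)
  trend <- .fit_dispersion_trend(alpha_mle, base_mean)
  alpha_trend <- pmin(pmax(trend$a0 + trend$a1 / pmax(base_mean, 1e-8),
                           exp(.LOG_ALPHA_LO)), exp(.LOG_ALPHA_HI))
  la_map <- nb_map_dispersions_cpp(m, design, offset, log(alpha_trend),
                                   prior_var, .LOG_ALPHA_LO, .LOG_ALPHA_HI)
  alpha_map <- exp(la_map)
  # taxa whose ML fit failed fall back to the trend value
  failed <- !is.finite(alpha_map)
  alpha_map[failed] <- alpha_trend[failed]
  nm <- colnames(m)
  list(alpha_mle = setNames(alpha_mle, nm),
       alpha_trend = setNames(alpha_trend, nm),
       alpha_map = setNames(alpha_map, nm),
       base_mean = setNames(base_mean, nm),
       trend_coef = c(a0 = trend$a0, a1 = trend$a1))
}

#' Fit one negative-binomial GLM at fixed dispersion
#'
#' Log-link IRLS fit with an offset; exposed mainly for verification (in
#' the Poisson limit `dispersion -> 0` it matches a Poisson GLM).
#'
#' @param y integer counts.
#' @param X design matrix.
#' @param offset per-sample offset on the log scale (e.g. log size
#'   factors).
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @return list with `beta`, `se`, `mu`, `loglik`, `converged`.
#' @export
nb_glm_fit <- function(y, X, offset = rep(0, length(y)), dispersion = 1e-8) {
  fit <- nb_glm_fit_cpp(as.numeric(y), as.matrix(X), as.numeric(offset),
                        dispersion)
  fit$beta <- setNames(as.numeric(fit$beta), colnames(X))
  fit$se <- setNames(as.numeric(fit$se), colnames(X))
  fit$mu <- as.numeric(fit$mu)
  fit
}

#' Negative-binomial Wald differential-abundance test
#'
#' Per taxon, an NB GLM is fitted on the design
#' `[intercept | covariates | condition]` with size-factor offsets and the
#' shrunken dispersions from [estimate_dispersions()]; the condition
#' coefficient is reported as a log2 fold change (natural-log coefficient
#' divided by ln 2), with Wald `z = coef/SE`, two-sided normal p-values and
#' BH adjustment across the taxa that converged (non-converged taxa are
#' flagged and excluded from the BH family).
#'
#' @param counts a `count_table` or samples x taxa count matrix.
#' @param condition 2-level per-sample labels (factor/logical); the second
#'   level (or TRUE) is the case group, so positive `log2_fc` means
#'   enriched in cases.
#' @param covariates optional per-sample data.frame of adjustment
#'   covariates (e.g. smoking as a 3-level factor, dummy-coded with
#'   "never" as reference).
#' @param alpha significance level recorded for downstream direction
#'   classification (default 0.05).
#' @param prior_var dispersion shrinkage prior variance (default 0.25).
#' @return data.frame of class `da_result` with columns `taxon`,
#'   `base_mean`, `log2_fc`, `se`, `wald_stat`, `p_value`, `p_adjusted`,
#'   `converged`.
#' @export
wald_test <- function(counts, condition, covariates = NULL, alpha = 0.05,
                      prior_var = 0.25) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (is.logical(condition)) condition <- factor(condition, c(FALSE, TRUE))
  condition <- droplevels(factor(condition))
  if (nlevels(condition) != 2)
    stop("condition must have exactly 2 levels")
  df <- data.frame(.cond = condition)
  terms <- ".cond"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(m))
      stop("covariates must align with samples")
    df <- cbind(covariates, df)
    terms <- c(names(covariates), ".cond")   # condition coefficient last
  }
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  X <- model.matrix(reformulate(terms), data = df)
  sf <- size_factors(m)
  disp <- estimate_dispersions(m, X, sf = sf, prior_var = prior_var)
  fits <- nb_wald_fits_cpp(m, X, log(sf), disp$alpha_map)
  p_idx <- ncol(X)   # condition coefficient
  beta <- fits$beta[p_idx, ]
  se <- fits$se[p_idx, ]
  conv <- fits$converged & is.finite(beta) & is.finite(se) & se > 0
  wald <- ifelse(conv, beta / se, NA_real_)
  pval <- ifelse(conv, 2 * pnorm(-abs(wald)), NA_real_)
  padj <- rep(NA_real_, length(pval))
  padj[conv] <- bh_adjust(pval[conv])$adjusted_p
  res <- data.frame(taxon = colnames(m),
                    base_mean = unname(disp$base_mean),
                    log2_fc = beta / log(2),
                    se = se / log(2),
                    wald_stat = wald,
                    p_value = pval,
                    p_adjusted = padj,
                    converged = conv,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "dispersions") <- disp$alpha_map
  class(res) <- c("da_result", "data.frame")
  res
}

#' Partition significant taxa by direction of change
#'
#' @param results a `da_result` from [wald_test()].
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list of class `direction_sets` with `increased`, `decreased`
#'   (taxa character vectors) and `alpha`.
#' @export
classify_directions <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("empty DA results")
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < alpha
  structure(list(increased = results$taxon[sig & results$log2_fc > 0],
                 decreased = results$taxon[sig & results$log2_fc < 0],
                 alpha = alpha),
            class = "direction_sets")
}

#' @export
print.direction_sets <- function(x, ...) {
  cat(sprintf("direction_sets: %d increased, %d decreased (alpha = %g)\n",
              length(x$increased), length(x$decreased), x$alpha))
  invisible(x)
}
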