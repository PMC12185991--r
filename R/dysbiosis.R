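# Mann-Whitney sensitivity pruning of the DA-derived direction sets and
# the per-sample log10 ratio dysbiosis index.

#' Mann-Whitney U test (exact or tie-corrected normal)
#'
#' Two-sided rank-sum test. When `n_x + n_y <= exact_limit` the p-value is
#' exact, by enumeration of all `choose(n_x + n_y, n_x)` group assignments
#' of the pooled values (valid under ties, where the permutation
#' distribution of U remains symmetric about `n_x n_y / 2`); otherwise a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact_limit largest pooled size for exact enumeration (default
#'   12).
#' @return list of class `mwu_result`: `u_statistic` (U for `x`),
#'   `p_value`, `n_x`, `n_y`, `method`.
#' @export
mwu_test <- function(x, y, exact_limit = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mid <- nx * ny / 2
  if (n <= exact_limit) {
    idx <- combn(n, nx)
    rsums <- colSums(matrix(r[idx], nrow = nx))
    u_all <- rsums - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mid) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  structure(list(u_statistic = u_obs, p_value = p, n_x = nx, n_y = ny,
                 method = method),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' Mann-Whitney sensitivity pruning of direction sets
#'
#' For every taxon in the increased or decreased set, its abundances are
#' compared between the two outcome groups with [mwu_test()]; taxa with a
#' p-value strictly greater than `p_threshold` are removed (taxa at
#' exactly the threshold are retained). Samples with a missing outcome are
#' ignored.
#'
#' @param table an [abundance_table()].
#' @param outcome per-sample binary labels (logical, NA allowed).
#' @param sets a `direction_sets` (see [classify_directions()]).
#' @param p_threshold pruning threshold (default 0.10).
#' @return A pruned `direction_sets`, with the per-taxon pruning p-values
#'   attached as attribute `"prune_p"` (named numeric).
#' @export
prune_sets <- function(table, outcome, sets, p_threshold = 0.10) {
  stopifnot(inherits(table, "abundance_table"))
  all_taxa <- c(sets$increased, sets$decreased)
  missing_taxa <- setdiff(all_taxa, taxa(table))
  if (length(missing_taxa))
    stop("taxa not in table: ", paste(missing_taxa, collapse = ", "))
  keep <- !is.na(outcome)
  grp <- as.logical(outcome[keep])
  p <- vapply(all_taxa, function(tx) {
    v <- table$values[keep, tx]
    mwu_test(v[grp], v[!grp])$p_value
  }, numeric(1))
  retained <- names(p)[p <= p_threshold]
  out <- structure(list(increased = intersect(sets$increased, retained),
                        decreased = intersect(sets$decreased, retained),
                        alpha = sets$alpha),
                   class = "direction_sets")
  attr(out, "prune_p") <- p
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Microbial dysbiosis index
#'
#' Per sample, `log10((sum of increased-taxa abundances + pc) /
#' (sum of decreased-taxa abundances + pc))`, where `pc` is a pseudocount
#' keeping the index finite when a sample lacks all taxa of one set. The
#' default pseudocount is half the smallest nonzero abundance in the
#' table; the value used is attached as attribute `"pseudocount"`.
#'
#' @param table an [abundance_table()].
#' @param sets a `direction_sets` with both sets non-empty.
#' @param pseudocount positive pseudocount (default half-minimum-nonzero).
#' @return named per-sample numeric index.
#' @export
dysbiosis_index <- function(table, sets, pseudocount = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (!length(sets$increased) || !length(sets$decreased))
    stop("both direction sets must be non-empty: the dysbiosis index is ",
         "undefined when either the increased or the decreased set is empty")
  missing_taxa <- setdiff(c(sets$increased, sets$decreased), taxa(table))
  if (length(missing_taxa))
    stop("taxa not in table: ", paste(missing_taxa, collapse = ", "))
  if (is.null(pseudocount)) {
    nz <- table$values[table$values > 0]
    if (!length(nz)) stop("table has no nonzero abundances")
    pseudocount <- min(nz) / 2
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  inc <- rowSums(table$values[, sets$increased, drop = FALSE])
  dec <- rowSums(table$values[, sets$decreased, drop = FALSE])
  idx <- log10((inc + pseudocount) / (dec + pseudocount))
  attr(idx, "pseudocount") <- pseudocount
  setNames(idx, sample_ids(table))
}
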