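# Spearman correlation structure among taxa: thresholded co-occurrence
# networks per outcome group and taxa x clinical-parameter correlation
# tables.

#' Spearman rank correlation with exact or t-approximate p-value
#'
#' Rho is the Pearson correlation of midranks. For `n <= 9` the two-sided
#' p-value is exact, by enumeration of all `n!` permutations (valid under
#' ties); for larger n it uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman's rho undefined")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .all_permutations(n)
    cx <- rx - mean(rx)
    cy <- ry - mean(ry)
    # rho for every permutation of x-ranks against fixed y-ranks
    num <- matrix(cx[perms], nrow = nrow(perms)) %*% cy
    rho_all <- num / sqrt(sum(cx^2) * sum(cy^2))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as an (n! x n) matrix, built by recursive
# insertion. n <= 9 keeps this below 3.3M cells.
.all_permutations <- function(n) {
  if (n > 9) stop("refusing to enumerate permutations for n > 9")
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    p <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(p[, seq_len(pos - 1), drop = FALSE], k,
            p[, seq.int(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  p
}

#' Thresholded Spearman co-occurrence network
#'
#' Nodes are the `top_n` most abundant taxa (by mean relative abundance in
#' the selected samples) united with any supplied differentially abundant
#' taxa. Undirected edges connect taxon pairs with `rho > rho_threshold`
#' (or `|rho| > rho_threshold` when `absolute = TRUE`) and
#' `p < p_threshold`; no multiple-testing correction is applied to edges
#' (a deliberately liberal raw-p rule).
#'
#' @param table an [abundance_table()].
#' @param subset optional logical or index sample mask (>= 4 samples).
#' @param rho_threshold correlation threshold (default 0.5).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @param top_n number of most-abundant taxa as nodes (default 50).
#' @param da_taxa optional taxa always included as nodes.
#' @param absolute use `|rho|` instead of signed rho (default FALSE).
#' @return list of class `correlation_network`: `nodes`, `edges`
#'   (data.frame taxon_a, taxon_b, rho, p_value, a < b canonical order)
#'   and the thresholds.
#' @export
cooccurrence_network <- function(table, subset = NULL, rho_threshold = 0.5,
                                 p_threshold = 0.05, top_n = 50,
                                 da_taxa = character(), absolute = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  vals <- table$values
  if (!is.null(subset)) vals <- vals[subset, , drop = FALSE]
  if (nrow(vals) < 4) stop("subset must select >= 4 samples")
  missing_taxa <- setdiff(da_taxa, colnames(vals))
  if (length(missing_taxa))
    stop("da_taxa not in table: ", paste(missing_taxa, collapse = ", "))
  top <- names(sort(colMeans(vals), decreasing = TRUE))
  nodes <- union(head(top, top_n), da_taxa)
  nodes <- nodes[order(match(nodes, colnames(vals)))]
  sub <- vals[, nodes, drop = FALSE]
  usable <- apply(sub, 2, sd) > 0
  edges <- data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  use_nodes <- nodes[usable]
  if (length(use_nodes) >= 2) {
    pairs <- combn(use_nodes, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      st <- spearman_test(sub[, a], sub[, b])
      crit <- if (absolute) abs(st$rho) else st$rho
      if (crit > rho_threshold && st$p_value < p_threshold) {
        ab <- sort(c(a, b))
        data.frame(taxon_a = ab[1], taxon_b = ab[2], rho = st$rho,
                   p_value = st$p_value, stringsAsFactors = FALSE)
      } else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  structure(list(nodes = nodes, edges = edges,
                 rho_threshold = rho_threshold, p_threshold = p_threshold,
                 absolute = absolute),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges (rho > %g, p < %g)\n",
              length(x$nodes), nrow(x$edges), x$rho_threshold, x$p_threshold))
  invisible(x)
}

#' Export a correlation network
#'
#' @param network a `correlation_network`.
#' @param graphml_path optional GraphML output path (via igraph).
#' @param edges_path optional edge-list TSV output path.
#' @return the `igraph` graph, invisibly.
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  if (!is.null(edges_path)) write_tsv(network$edges, edges_path)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}

#' Taxa x clinical-parameter Spearman correlation table
#'
#' @param table an [abundance_table()].
#' @param meta metadata data.frame aligned with the table's samples.
#' @param taxa_names taxa to correlate (default: all in `table`).
#' @param parameters names of numeric metadata columns.
#' @return long data.frame with `taxon`, `parameter`, `rho`, `p_value`.
#' @export
taxon_clinical_correlations <- function(table, meta,
                                        taxa_names = taxa(table),
                                        parameters) {
  stopifnot(inherits(table, "abundance_table"))
  bad <- setdiff(parameters, names(meta))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  res <- lapply(taxa_names, function(tx) {
    v <- table$values[, tx]
    do.call(rbind, lapply(parameters, function(pm) {
      y <- meta[[pm]]
      keep <- !is.na(y)
      st <- spearman_test(v[keep], y[keep])
      data.frame(taxon = tx, parameter = pm, rho = st$rho,
                 p_value = st$p_value, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, res)
}
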