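# Taxonomic ranks in lineage order. MetaPhlAn lineages use pipe-delimited
# prefixed segments (k__...|p__...|...|s__...); "d__" (domain) is accepted as
# a synonym for "k__".
.RANKS <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
            family = "f__", genus = "g__", species = "s__")

#' Samples-by-taxa relative abundance table
#'
#' Container for a relative-abundance matrix on the MetaPhlAn percent scale
#' (0-100 per sample), with lineage-annotated taxa at a single taxonomic
#' rank. Rows are samples, columns are taxa.
#'
#' @param values numeric matrix, samples x taxa, with unique rownames
#'   (sample ids) and colnames (pipe-delimited lineages).
#' @param rank character scalar, one of `"kingdom"`, `"phylum"`, `"class"`,
#'   `"order"`, `"family"`, `"genus"`, `"species"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `values` and `rank`.
#' @export
abundance_table <- function(values, rank) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample rownames and taxon colnames")
  rank <- match.arg(rank, names(.RANKS))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxa: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative")
  totals <- rowSums(values)
  if (any(totals > 100 + 1e-6))
    stop("per-sample totals exceed 100 (percent scale): ",
         paste(head(rownames(values)[totals > 100 + 1e-6], 3), collapse = ", "))
  structure(list(values = values, rank = rank), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (rank: %s)\n",
              nrow(x$values), ncol(x$values), x$rank))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
taxa <- function(x) colnames(x$values)

#' Terminal rank of a lineage string
#'
#' @param lineage character vector of pipe-delimited lineages.
#' @return character vector of rank names.
#' @keywords internal
lineage_rank <- function(lineage) {
  last <- vapply(strsplit(lineage, "|", fixed = TRUE),
                 function(p) p[[length(p)]], character(1))
  pref <- substr(last, 1, 3)
  pref[pref == "d__"] <- "k__"
  rk <- names(.RANKS)[match(pref, .RANKS)]
  if (anyNA(rk))
    stop("malformed lineage (no rank prefix): ",
         paste(head(lineage[is.na(rk)], 3), collapse = ", "))
  rk
}

#' Read a MetaPhlAn-style merged abundance table
#'
#' Parses the merged-profile TSV dialect: a lineage column (`clade_name`,
#' possibly `#`-prefixed) followed by one column per sample, values on the
#' percent scale, rows at mixed taxonomic ranks. Only rows whose terminal
#' rank matches `rank` are returned. Comment lines beginning `#` are
#' stripped (a `#clade_name` header line is recognised as the header).
#'
#' @param path path to the TSV file.
#' @param rank taxonomic rank to extract (see [abundance_table()]).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, rank = "species") {
  rank <- match.arg(rank, names(.RANKS))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(lines, "#")
  header_idx <- which(is_comment & grepl("clade_name", lines, fixed = TRUE))
  if (length(header_idx)) {
    header <- sub("^#\\s*", "", lines[max(header_idx)])
    body <- lines[!is_comment]
  } else {
    body <- lines[!is_comment]
    if (!length(body)) stop("no data rows in ", path)
    header <- body[1]
    body <- body[-1]
  }
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 2) stop("expected a lineage column and >= 1 sample column")
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop("row ", bad[1], " has ", lengths(fields)[bad[1]], " fields, expected ",
         length(cols))
  lineage <- vapply(fields, `[[`, character(1), 1)
  vals <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric abundance in row for ", f[1])
    v
  }, numeric(length(cols) - 1))
  # vals is samples x rows already when >1 sample; normalize orientation
  vals <- matrix(vals, nrow = length(cols) - 1, ncol = length(lineage),
                 dimnames = list(cols[-1], lineage))
  if (any(vals < 0)) {
    j <- which(colSums(vals < 0) > 0)[1]
    stop("negative abundance in row for ", lineage[j])
  }
  rk <- lineage_rank(lineage)
  keep <- rk == rank
  if (!any(keep)) stop("no rows at rank '", rank, "' in ", path)
  abundance_table(vals[, keep, drop = FALSE], rank = rank)
}

#' Write an abundance table as a canonical merged-profile TSV
#'
#' Writes taxa as rows with a `clade_name` column. Values are serialized
#' with 17 significant digits so that read -> write -> read round-trips are
#' bit identical.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  m <- t(table$values)                      # taxa x samples on disk
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("clade_name", colnames(m)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], digits = 17, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Aggregate an abundance table to an ancestor rank
#'
#' Sums, per sample, the abundances of all taxa sharing the same
#' truncated lineage at `target_rank`. Per-sample totals are conserved
#' exactly, so species -> genus -> family equals species -> family.
#'
#' @param table an [abundance_table()].
#' @param target_rank ancestor rank to aggregate to.
#' @return An [abundance_table()] at `target_rank`.
#' @export
aggregate_taxonomy <- function(table, target_rank) {
  stopifnot(inherits(table, "abundance_table"))
  target_rank <- match.arg(target_rank, names(.RANKS))
  from <- match(table$rank, names(.RANKS))
  to <- match(target_rank, names(.RANKS))
  if (to > from)
    stop("target_rank '", target_rank, "' is not an ancestor of '", table$rank, "'")
  if (to == from) return(table)
  trunc <- vapply(strsplit(taxa(table), "|", fixed = TRUE), function(p) {
    pref <- substr(p, 1, 3)
    pref[pref == "d__"] <- "k__"
    i <- match(.RANKS[[to]], pref)
    if (is.na(i)) stop("lineage lacks rank '", target_rank, "': ",
                       paste(p, collapse = "|"))
    paste(p[seq_len(i)], collapse = "|")
  }, character(1))
  groups <- unique(trunc)
  agg <- vapply(groups, function(g)
    rowSums(table$values[, trunc == g, drop = FALSE]), numeric(nrow(table$values)))
  if (nrow(table$values) == 1L)
    agg <- matrix(agg, nrow = 1, dimnames = list(sample_ids(table), groups))
  abundance_table(agg, rank = target_rank)
}

#' Convert percent abundances to pseudo-counts
#'
#' Negative-binomial models require integer counts; MetaPhlAn profiles are
#' percentages. Each sample is scaled to a fixed sequencing depth:
#' `counts = round(values / 100 * scale_depth)`.
#'
#' @param table an [abundance_table()].
#' @param scale_depth per-sample total used for conversion (default 1e5).
#' @return A `count_table`: list with `counts` (samples x taxa integer
#'   matrix) and `scale_depth`.
#' @export
to_counts <- function(table, scale_depth = 1e5) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(scale_depth) || length(scale_depth) != 1 || scale_depth < 1)
    stop("`scale_depth` must be a positive integer scalar")
  counts <- round(table$values / 100 * scale_depth)
  structure(list(counts = counts, scale_depth = scale_depth),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (scale depth %g)\n",
              nrow(x$counts), ncol(x$counts), x$scale_depth))
  invisible(x)
}

#' Drop rare taxa by prevalence
#'
#' Taxa present (abundance > 0) in fewer than `min_prevalence` of samples
#' are removed; rare-taxon negative-binomial fits are unstable and such taxa
#' carry little information for the index.
#'
#' @param table an [abundance_table()].
#' @param min_prevalence minimum fraction of samples with nonzero abundance
#'   (default 0.10).
#' @return A filtered [abundance_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  stopifnot(inherits(table, "abundance_table"))
  prev <- colMeans(table$values > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("prevalence filter removed all taxa")
  abundance_table(table$values[, keep, drop = FALSE], rank = table$rank)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: after sorting ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return A list with `raw_p`, `adjusted_p` and `method = "BH"`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  structure(list(raw_p = p, adjusted_p = p.adjust(p, method = "BH"),
                 method = "BH"),
            class = "multiple_testing_result")
}
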