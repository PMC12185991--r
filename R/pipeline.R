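# End-to-end orchestration: (simulate | ingest) -> diversity -> DA ->
# prune -> index -> associate -> network, with one root seed, per-stage
# logging and a machine-readable run report.

#' Default pipeline configuration
#'
#' Returned as a plain list; [run_pipeline()] accepts such a list or the
#' path to a YAML file with the same fields. One root seed drives every
#' stage through fixed offsets.
#'
#' @param simulate generate a synthetic cohort instead of reading files.
#' @param abundance,metadata input TSV paths when `simulate = FALSE`.
#' @param outdir output directory (created if missing); NULL disables
#'   file output.
#' @param seed root seed.
#' @param rank taxonomic rank analysed.
#' @param min_prevalence prevalence filter for DA and the index.
#' @param scale_depth pseudo-count conversion depth.
#' @param da_alpha BH significance threshold for direction sets.
#' @param prune_p Mann-Whitney pruning threshold.
#' @param n_perm PERMANOVA permutations.
#' @param permanova_covariates metadata columns adjusted for in PERMANOVA.
#' @param network_top_n node count for co-occurrence networks.
#' @param sim overrides passed to [sim_config()].
#' @return configuration list.
#' @export
pipeline_config <- function(simulate = TRUE, abundance = NULL, metadata = NULL,
                            outdir = NULL, seed = 1, rank = "species",
                            min_prevalence = 0.10, scale_depth = 1e5,
                            da_alpha = 0.05, prune_p = 0.10, n_perm = 999,
                            permanova_covariates = c("age", "bmi", "smoking"),
                            network_top_n = 50, sim = list()) {
  as.list(environment())
}

.stage_seeds <- function(root) {
  # fixed documented splitting: stage k uses root * 13 + k (kept < 2^31)
  setNames((as.integer(root) %% 100000L) * 13L + 1:6,
           c("simulate", "diversity", "da", "index", "associate", "network"))
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a simulated or an ingested
#' cohort and returns (and optionally writes) a run report: per-stage
#' sample/taxon counts, direction sets before and after pruning, the
#' per-model association results and the seeds used. Identical
#' configuration and seed give an identical report. If pruning empties
#' either direction set the pipeline stops before association with status
#' `"undefined-index"` (the log10 ratio is undefined); if the DA stage
#' finds no significant taxa at all, status is `"no-significant-taxa"`.
#'
#' @param config a list from [pipeline_config()] or a YAML file path.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- utils::modifyList(pipeline_config(),
                                                        yaml::read_yaml(config))
  seeds <- .stage_seeds(config$seed)
  log <- character()

  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, config$sim %||% list())
    cohort <- generate_cohort(scfg, seed = seeds[["simulate"]])
    abund <- cohort$abundance
    meta <- cohort$metadata
    truth <- cohort$truth
    log <- .log_stage(log, "simulate",
                      sprintf("n=%d samples, %d taxa", nrow(abund$values),
                              ncol(abund$values)))
  } else {
    abund <- read_abundance_table(config$abundance, rank = config$rank)
    meta <- read_metadata(config$metadata)
    out <- derive_outcomes(meta)
    meta$fev1_decline_ml_per_year <- out$fev1_decline_ml_per_year
    meta$rapid_decline <- out$rapid_decline
    meta$airflow_limitation <- out$airflow_limitation
    truth <- NULL
    m <- match(sample_ids(abund), meta$sample_id)
    if (anyNA(m)) stop("metadata missing for ", sum(is.na(m)), " samples")
    meta <- meta[m, , drop = FALSE]
    log <- .log_stage(log, "ingest",
                      sprintf("n=%d samples, %d taxa", nrow(abund$values),
                              ncol(abund$values)))
  }

  has_outcome <- !is.na(meta$rapid_decline)
  log <- .log_stage(log, "outcomes", sprintf(
    "%d with valid follow-up of %d; %d rapid decliners (%.1f%%); %d airflow limited",
    sum(has_outcome), nrow(meta), sum(meta$rapid_decline, na.rm = TRUE),
    100 * mean(meta$rapid_decline, na.rm = TRUE),
    sum(meta$airflow_limitation)))

  # diversity on the full table
  alpha_tab <- alpha_diversity(abund)
  alpha_mwu <- alpha_diversity_test(setNames(alpha_tab$shannon, alpha_tab$sample_id),
                                    meta$rapid_decline)
  d <- bray_curtis_matrix(abund)
  ord <- pcoa(d, n_axes = 2)
  perm <- permanova(d, meta$rapid_decline,
                    covariates = meta[, config$permanova_covariates, drop = FALSE],
                    n_perm = config$n_perm, seed = seeds[["diversity"]])
  log <- .log_stage(log, "diversity", sprintf(
    "Shannon MWU p=%.3g; PERMANOVA group p=%.3g",
    alpha_mwu$p_value, perm$p_value[perm$term == "group"]))

  # differential abundance on the filtered, outcome-complete subset
  filt <- prevalence_filter(abund, config$min_prevalence)
  sub <- abundance_table(filt$values[has_outcome, , drop = FALSE], filt$rank)
  counts <- to_counts(sub, config$scale_depth)
  da <- wald_test(counts, condition = meta$rapid_decline[has_outcome],
                  covariates = data.frame(smoking = meta$smoking[has_outcome]),
                  alpha = config$da_alpha)
  sets <- classify_directions(da, alpha = config$da_alpha)
  log <- .log_stage(log, "da", sprintf(
    "%d taxa tested (prevalence >= %g); %d increased, %d decreased at BH < %g",
    nrow(da), config$min_prevalence, length(sets$increased),
    length(sets$decreased), config$da_alpha))

  report <- list(config = config, seeds = as.list(seeds), log = log,
                 n_samples = nrow(abund$values), n_taxa = ncol(abund$values),
                 n_followup = sum(has_outcome),
                 n_rapid = sum(meta$rapid_decline, na.rm = TRUE),
                 n_airflow = sum(meta$airflow_limitation),
                 alpha_shannon_p = alpha_mwu$p_value,
                 permanova = perm,
                 da = da, sets_raw = sets, truth = truth,
                 version = as.character(utils::packageVersion("dysbiome")))
  class(report) <- "run_report"

  if (!length(sets$increased) && !length(sets$decreased)) {
    report$status <- "no-significant-taxa"
    report$log <- .log_stage(report$log, "index",
                             "no significant taxa; stopping before index")
    return(.finalize_report(report, abund, alpha_tab, ord))
  }

  pruned <- prune_sets(sub, meta$rapid_decline[has_outcome], sets,
                       p_threshold = config$prune_p)
  report$sets_pruned <- pruned
  report$log <- .log_stage(report$log, "prune", sprintf(
    "retained %d of %d taxa at MWU p <= %g",
    length(pruned$increased) + length(pruned$decreased),
    length(sets$increased) + length(sets$decreased), config$prune_p))

  if (!length(pruned$increased) || !length(pruned$decreased)) {
    report$status <- "undefined-index"
    report$log <- .log_stage(report$log, "index",
                             "a pruned direction set is empty; index undefined")
    return(.finalize_report(report, abund, alpha_tab, ord))
  }

  index <- dysbiosis_index(filt, pruned)
  report$index <- as.numeric(index)
  names(report$index) <- names(index)
  report$pseudocount <- attr(index, "pseudocount")
  report$log <- .log_stage(report$log, "index", sprintf(
    "per-sample index computed (pseudocount %.4g)", report$pseudocount))

  assoc_rapid <- tryCatch(run_models(index, meta, outcome = "rapid"),
                          error = function(e)
                            stop("stage associate failed: ",
                                 conditionMessage(e), call. = FALSE))
  assoc_air <- tryCatch(run_models(index, meta, outcome = "airflow"),
                        error = function(e)
                          stop("stage associate failed: ",
                               conditionMessage(e), call. = FALSE))
  report$association <- rbind(assoc_rapid, assoc_air)
  report$log <- .log_stage(report$log, "associate", sprintf(
    "model1 aOR=%.3f [%.3f, %.3f], p=%.3g (n=%d)",
    assoc_rapid$aOR[1], assoc_rapid$ci_low[1], assoc_rapid$ci_high[1],
    assoc_rapid$p_value[1], assoc_rapid$n_used[1]))

  da_taxa <- c(pruned$increased, pruned$decreased)
  report$network_rapid <- cooccurrence_network(
    sub, subset = meta$rapid_decline[has_outcome] %in% TRUE,
    top_n = config$network_top_n, da_taxa = da_taxa)
  report$network_normal <- cooccurrence_network(
    sub, subset = meta$rapid_decline[has_outcome] %in% FALSE,
    top_n = config$network_top_n, da_taxa = da_taxa)
  report$log <- .log_stage(report$log, "network", sprintf(
    "%d edges (rapid), %d edges (normal)", nrow(report$network_rapid$edges),
    nrow(report$network_normal$edges)))
  report$taxon_clinical <- taxon_clinical_correlations(
    sub, meta[has_outcome, , drop = FALSE], taxa_names = da_taxa,
    parameters = c("age", "bmi", "hiv_duration", "cart_years",
                   "il1b_pg_ml", "il10_pg_ml"))
  report$status <- "ok"
  .finalize_report(report, abund, alpha_tab, ord, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.finalize_report <- function(report, abund, alpha_tab, ord, meta = NULL) {
  outdir <- report$config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(alpha_tab, file.path(outdir, "alpha_diversity.tsv"))
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, row.names = NULL)
    write_tsv(coords, file.path(outdir, "pcoa_coordinates.tsv"))
    write_tsv(report$permanova, file.path(outdir, "permanova.tsv"))
    write_tsv(as.data.frame(report$da), file.path(outdir, "da_species.tsv"))
    if (!is.null(report$index))
      write_tsv(data.frame(sample_id = names(report$index),
                           dysbiosis_index = report$index),
                file.path(outdir, "dysbiosis_index.tsv"))
    if (!is.null(report$association))
      write_tsv(report$association, file.path(outdir, "association.tsv"))
    if (!is.null(report$taxon_clinical))
      write_tsv(report$taxon_clinical,
                file.path(outdir, "taxa_clinical_correlations.tsv"))
    if (!is.null(report$network_rapid)) {
      export_network(report$network_rapid,
                     graphml_path = file.path(outdir, "network_rapid.graphml"),
                     edges_path = file.path(outdir, "network_rapid_edges.tsv"))
      export_network(report$network_normal,
                     graphml_path = file.path(outdir, "network_normal.graphml"),
                     edges_path = file.path(outdir, "network_normal_edges.tsv"))
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Serializable view of a run report
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return plain list that round-trips through JSON.
#' @export
report_to_json <- function(report) {
  sets_list <- function(s) {
    if (is.null(s)) return(NULL)
    out <- list(increased = as.list(s$increased),
                decreased = as.list(s$decreased))
    if (!is.null(attr(s, "prune_p")))
      out$prune_p <- as.list(attr(s, "prune_p"))
    out
  }
  list(status = report$status,
       seeds = report$seeds,
       n_samples = report$n_samples, n_taxa = report$n_taxa,
       n_followup = report$n_followup, n_rapid = report$n_rapid,
       n_airflow = report$n_airflow,
       alpha_shannon_p = report$alpha_shannon_p,
       permanova = report$permanova,
       sets_raw = sets_list(report$sets_raw),
       sets_pruned = sets_list(report$sets_pruned),
       pseudocount = report$pseudocount,
       association = report$association,
       log = as.list(report$log),
       version = report$version)
}

#' @export
print.run_report <- function(x, ...) {
  cat("dysbiome run report (status:", x$status, ")\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
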