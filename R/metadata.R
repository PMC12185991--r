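# Clinical metadata: one row per sample, sample_id first column.

.META_NUMERIC <- c("fev1_baseline_ml", "fev1_followup_ml", "fvc_baseline_ml",
                   "followup_years", "fev1_pct_predicted", "age", "bmi",
                   "hiv_duration", "cart_years", "il1b_pg_ml", "il10_pg_ml")
.META_REQUIRED <- c("sample_id", .META_NUMERIC, "smoking", "sex", "ethnicity",
                    "transmission_mode", "nadir_cd4_lt200", "pneumonia_history",
                    "spiro_grade")
.SMOKING_LEVELS <- c("never", "former", "current")

#' Validate cohort metadata
#'
#' Checks the per-sample clinical covariate table: unique sample ids,
#' required columns, smoking in \{current, former, never\}, spirometry
#' quality grades in A-F, positive follow-up interval whenever follow-up
#' spirometry is present.
#'
#' @param meta data.frame of per-sample covariates.
#' @return `meta`, with categorical columns coerced to factors
#'   (smoking reference level "never").
#' @export
validate_metadata <- function(meta) {
  missing_cols <- setdiff(.META_REQUIRED, names(meta))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  if (!all(meta$smoking %in% .SMOKING_LEVELS))
    stop("smoking must be one of: ", paste(.SMOKING_LEVELS, collapse = ", "))
  if (!all(meta$spiro_grade %in% LETTERS[1:6]))
    stop("spiro_grade must be a letter A-F")
  has_fu <- !is.na(meta$fev1_followup_ml)
  if (any(has_fu & (is.na(meta$followup_years) | meta$followup_years <= 0)))
    stop("followup_years must be > 0 whenever follow-up spirometry is present")
  meta$smoking <- factor(meta$smoking, levels = .SMOKING_LEVELS)
  meta$sex <- factor(meta$sex, levels = c("female", "male"))
  meta$ethnicity <- factor(meta$ethnicity, levels = c("caucasian", "other"))
  meta$transmission_mode <- factor(meta$transmission_mode)
  meta$nadir_cd4_lt200 <- as.logical(meta$nadir_cd4_lt200)
  meta$pneumonia_history <- as.logical(meta$pneumonia_history)
  meta
}

#' Read a cohort metadata TSV
#'
#' One header row, sample id in the first column; see
#' [validate_metadata()] for the expected fields.
#'
#' @param path path to the TSV.
#' @return A validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
  names(meta)[1] <- "sample_id"
  validate_metadata(meta)
}

#' Write a metadata (or any analysis) table as canonical TSV
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
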