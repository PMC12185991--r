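# Outcome derivation from spirometry and multivariable logistic association
# of the dysbiosis index with rapid lung-function decline and airflow
# limitation.

#' Derive lung-function outcomes from spirometry
#'
#' The primary outcome, rapid lung function decline, is an FEV1 decline
#' strictly greater than 40 mL/year between the two visits:
#' `decline = (fev1_baseline - fev1_followup) / followup_years`. Samples
#' without follow-up spirometry get a missing `rapid_decline`. The
#' secondary outcome, airflow limitation, is FEV1/FVC < 0.70 together with
#' FEV1 below 80% of the predicted value (moderate-or-worse obstruction).
#'
#' @param meta validated metadata data.frame (see [validate_metadata()]).
#' @return data.frame with `sample_id`, `fev1_decline_ml_per_year`,
#'   `rapid_decline` (logical, NA without follow-up) and
#'   `airflow_limitation` (logical).
#' @export
derive_outcomes <- function(meta) {
  has_fu <- !is.na(meta$fev1_followup_ml)
  if (any(has_fu & (is.na(meta$followup_years) | meta$followup_years <= 0)))
    stop("followup_years must be > 0 whenever follow-up spirometry is present")
  decline <- rep(NA_real_, nrow(meta))
  decline[has_fu] <- (meta$fev1_baseline_ml[has_fu] -
                        meta$fev1_followup_ml[has_fu]) /
    meta$followup_years[has_fu]
  rapid <- ifelse(has_fu, decline > 40, NA)
  ratio <- meta$fev1_baseline_ml / meta$fvc_baseline_ml
  airflow <- ratio < 0.70 & meta$fev1_pct_predicted < 80
  data.frame(sample_id = meta$sample_id,
             fev1_decline_ml_per_year = decline,
             rapid_decline = rapid,
             airflow_limitation = airflow,
             stringsAsFactors = FALSE)
}

#' Maximum-likelihood logistic regression
#'
#' Binomial GLM fit by iteratively reweighted least squares, with explicit
#' rank and separation checks. Standard errors come from the inverse
#' observed information at the optimum.
#'
#' @param y binary response (0/1 or logical) with both classes present.
#' @param X design matrix (including the intercept column).
#' @return list with `coefficients`, `se`, `loglik`, `fitted`, `n`.
#' @export
logistic_fit <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (length(unique(y)) < 2) stop("y must contain both classes")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X))]
    stop("design matrix is rank deficient (aliased: ",
         paste(colnames(X)[drop_idx], collapse = ", "), ")")
  }
  # the 0/1-fitted-probability warning is superseded by the explicit
  # separation check below
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  worst <- colnames(X)[which.max(abs(beta))]
  if (any(!is.finite(beta)) || max(abs(beta)) > 15)
    stop("perfect separation suspected (diverging coefficient for ",
         worst, ")")
  if (all((2 * y - 1) * eta > 0))   # a separating hyperplane exists
    stop("perfect separation detected (term ", worst,
         " classifies every observation)")
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(info)),
                   error = function(e) stop("information matrix singular"))
  se <- sqrt(diag(vcov))
  names(se) <- colnames(X)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  list(coefficients = beta, se = se, loglik = ll, fitted = mu, n = length(y))
}

# Build a model frame for one logistic model; drops (and counts) samples
# with any missing required variable. Returns NULL-design on degenerate data.
.build_design <- function(df, terms) {
  keep <- complete.cases(df[, c("outcome", terms), drop = FALSE])
  d <- df[keep, , drop = FALSE]
  X <- model.matrix(reformulate(terms), data = d)
  list(y = as.numeric(d$outcome), X = X, n_used = nrow(d),
       n_dropped = nrow(df) - nrow(d))
}

# One logistic model -> one association_result row for the index term.
.fit_model <- function(df, terms, model_label) {
  des <- .build_design(df, terms)
  fit <- logistic_fit(des$y, des$X)
  i <- match("index", names(fit$coefficients))
  coef <- fit$coefficients[i]
  se <- fit$se[i]
  z <- coef / se
  data.frame(model = model_label, term = "index",
             coefficient = coef, se = se,
             aOR = exp(coef),
             ci_low = exp(coef - 1.96 * se),
             ci_high = exp(coef + 1.96 * se),
             p_value = 2 * pnorm(-abs(z)),
             n_used = des$n_used, n_dropped = des$n_dropped,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multivariable association of the dysbiosis index with an outcome
#'
#' For the rapid-decline outcome: model 1 adjusts for smoking status and
#' traditional (age, sex, BMI, ethnicity) and HIV-related (transmission
#' mode, nadir CD4 < 200, HIV duration) risk factors; model 2 additionally
#' adjusts for IL-1beta and IL-10; sensitivity fits repeat model 1 on the
#' pneumonia-history-free subset and on the high-quality-spirometry
#' (grade A-C) subset. For the airflow-limitation outcome (low case
#' counts), a family of small models each adjusts for age, BMI and one
#' further covariate at a time (default smoking, HIV duration, cART years).
#' Samples missing any covariate required by a model are dropped from that
#' model only; `n_used` is reported per model. The index enters
#' untransformed (per unit of the log10 ratio) and 95% CIs are Wald
#' intervals on the log-odds scale.
#'
#' @param index named per-sample dysbiosis index (names = sample ids).
#' @param meta validated metadata, including derived outcome columns
#'   `rapid_decline` and `airflow_limitation` (see [derive_outcomes()]).
#' @param outcome `"rapid"` or `"airflow"`.
#' @param airflow_third covariates rotated as the third adjustment in
#'   airflow models.
#' @return data.frame of association results, one row per model.
#' @export
run_models <- function(index, meta, outcome = c("rapid", "airflow"),
                       airflow_third = c("smoking", "hiv_duration", "cart_years")) {
  outcome <- match.arg(outcome)
  if (is.null(names(index))) stop("`index` must be named by sample id")
  m <- match(meta$sample_id, names(index))
  if (anyNA(m)) stop("index missing for ", sum(is.na(m)), " samples")
  df <- meta
  df$index <- as.numeric(index)[m]
  if (outcome == "rapid") {
    df$outcome <- df$rapid_decline
    model1 <- c("index", "smoking", "age", "sex", "bmi", "ethnicity",
                "transmission_mode", "nadir_cd4_lt200", "hiv_duration")
    model2 <- c(model1, "il1b_pg_ml", "il10_pg_ml")
    res <- rbind(
      .fit_model(df, model1, "model1"),
      .fit_model(df, model2, "model2"),
      .fit_model(df[!df$pneumonia_history, , drop = FALSE], model1,
                 "sensitivity-pneumonia"),
      .fit_model(df[df$spiro_grade %in% c("A", "B", "C"), , drop = FALSE],
                 model1, "sensitivity-quality"))
  } else {
    df$outcome <- df$airflow_limitation
    res <- do.call(rbind, lapply(airflow_third, function(third)
      .fit_model(df, c("index", "age", "bmi", third),
                 paste0("airflow+", third))))
  }
  res
}
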