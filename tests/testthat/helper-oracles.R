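# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle follows the textbook definition directly and shares no code
# with the package implementation it checks.

# BH step-up from the definition: sort ascending, running minimum of
# p_(j) * m / j from the top, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0)))
    q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# Exact two-sided Mann-Whitney p by direct enumeration; U computed by
# pairwise comparison counting (not ranks).
mwu_u_pairwise <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
mwu_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  mid <- nx * length(y) / 2
  u_obs <- mwu_u_pairwise(x, y)
  subsets <- utils::combn(n, nx)
  u_all <- apply(subsets, 2, function(idx)
    mwu_u_pairwise(pooled[idx], pooled[-idx]))
  list(u = u_obs,
       p = mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9))
}

# Exact two-sided Spearman p by enumerating permutations recursively,
# with rho computed via cor() on midranks.
perms_recursive <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms_recursive(v[-i]), function(p) c(v[i], p)))
  out
}
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  rho_all <- vapply(perms_recursive(rx), function(p) cor(p, ry), numeric(1))
  list(rho = rho, p = mean(abs(rho_all) >= abs(rho) - 1e-12))
}

# Logistic MLE for intercept + one predictor by nested grid search over
# the log-likelihood (three refinement rounds).
logistic_grid_oracle <- function(y, x) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; half <- 8
  for (round in 1:6) {
    g0 <- seq(c0 - half, c0 + half, length.out = 41)
    g1 <- seq(c1 - half, c1 + half, length.out = 41)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c0 <- g0[best[1]]; c1 <- g1[best[2]]
    half <- half / 8
  }
  c(intercept = c0, slope = c1)
}

# Tiny abundance table at species rank, built in code.
make_species_table <- function() {
  vals <- matrix(c(10, 5, 0.5,
                   2,  8, 1.5,
                   4,  4, 4), nrow = 3, byrow = TRUE)
  rownames(vals) <- c("A", "B", "C")
  colnames(vals) <- c(
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_vulgatus",
    "k__Bacteria|p__Bacteroidetes|c__Bacteroidia|o__Bacteroidales|f__Bacteroidaceae|g__Bacteroides|s__Bacteroides_dorei",
    "k__Bacteria|p__Firmicutes|c__Clostridia|o__Clostridiales|f__Lachnospiraceae|g__Blautia|s__Blautia_obeum")
  abundance_table(vals, rank = "species")
}

# Minimal valid metadata row set for association tests.
make_metadata <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    fev1_baseline_ml = rnorm(n, 3200, 400),
    fev1_followup_ml = rnorm(n, 3100, 400),
    fvc_baseline_ml = rnorm(n, 4200, 500),
    followup_years = runif(n, 1.5, 3),
    fev1_pct_predicted = runif(n, 60, 110),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    age = rnorm(n, 53, 10),
    sex = sample(c("male", "female"), n, TRUE),
    bmi = rnorm(n, 25, 3),
    ethnicity = sample(c("caucasian", "other"), n, TRUE, prob = c(.9, .1)),
    transmission_mode = sample(c("msm", "heterosexual", "other"), n, TRUE),
    nadir_cd4_lt200 = runif(n) < 0.3,
    hiv_duration = runif(n, 1, 30),
    cart_years = runif(n, 1, 25),
    il1b_pg_ml = rlnorm(n, log(0.2), 0.5),
    il10_pg_ml = rlnorm(n, log(0.8), 0.5),
    pneumonia_history = runif(n) < 0.4,
    spiro_grade = sample(LETTERS[1:6], n, TRUE, prob = c(.5, .25, .1, .07, .05, .03)),
    stringsAsFactors = FALSE)
}
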