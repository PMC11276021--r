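# shared fixtures and independent oracles used across the suite

# brute-force HC0 sandwich: explicit triple product evaluated term by term
brute_hc0 <- function(X, r) {
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(nrow(X)))
    meat <- meat + r[i]^2 * (X[i, ] %o% X[i, ])
  bread %*% meat %*% bread
}

# Hardy-Weinberg chi-square goodness-of-fit p-value from genotype counts
hw_chisq_p <- function(g) {
  n <- length(g)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expd < 1e-12)) return(NA_real_)
  x2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# minimal summary-statistics table for meta/discover tests
make_sumstats <- function(n = 10, seed = 1, n_samples = 5000L) {
  set.seed(seed)
  se_main <- runif(n, 0.2, 0.5)
  se_int <- runif(n, 0.4, 0.9)
  rho <- runif(n, -0.3, 0.3)
  data.table::data.table(
    SNPID = sprintf("var%05d", seq_len(n)),
    CHR = rep_len(1:4, n), POS = 1000000L * seq_len(n),
    EA = rep_len(c("A", "C", "G", "T"), n),
    OA = rep_len(c("C", "G", "T", "A"), n),
    EAF = runif(n, 0.05, 0.95), N = n_samples,
    BETA_MARG = rnorm(n, 0, 0.3), SE_MARG = runif(n, 0.1, 0.4),
    BETA_MAIN = rnorm(n, 0, 0.3), SE_MAIN = se_main,
    BETA_INT = rnorm(n, 0, 0.5), SE_INT = se_int,
    COV_MAIN_INT = rho * se_main * se_int,
    P_MARG = runif(n), P_MAIN = runif(n), P_INT = runif(n),
    P_JOINT = runif(n),
    DF_TOT = runif(n, 50, 500), DF_EXP = runif(n, 25, 100),
    DF_UNEXP = runif(n, 40, 400))
}

# meta-style table with the columns discover_loci needs
make_meta_table <- function(n = 10, seed = 1, n_samples = 30000L,
                            k_cohorts = 3L) {
  tab <- make_sumstats(n, seed, n_samples)
  tab$K_COHORTS <- k_cohorts
  tab$BETA_MAIN_2DF <- tab$BETA_MAIN
  tab$BETA_INT_2DF <- tab$BETA_INT
  tab$SE_MAIN_2DF <- tab$SE_MAIN
  tab$SE_INT_2DF <- tab$SE_INT
  tab$CHISQ_JOINT <- stats::qchisq(tab$P_JOINT, 2, lower.tail = FALSE)
  tab$DIRECTIONS <- strrep("+", k_cohorts)
  tab
}

# small fully-simulated harmonized cohort reused by several tests
small_cohort <- function(n = 600, m = 30, seed = 5, effect_table = NULL,
                         maf = NULL) {
  cfg <- sim_config(n_samples = n, n_variants = m,
                    maf_range = c(0.1, 0.5), maf = maf,
                    populations = "EUR", divergence = 0,
                    effect_table = effect_table, seed = seed)
  harmonize_cohort(simulate_cohort(cfg))
}
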