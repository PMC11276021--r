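# Shared demo-study configuration for the numbered analysis scripts.
# Three cohorts in two population groups, a 500-variant panel, and three
# planted effects: a short-sleep interaction on SBP, a marginal-only signal,
# and a long-sleep interaction on DBP. Every script re-derives what it needs
# deterministically from these settings, so the scripts can be run in order
# or individually.

library(gxesleep)

RESULTS <- file.path("results")
SEED <- 1L

COHORTS <- data.frame(
  name = c("eur1", "eur2", "his1"),
  population = c("EUR", "EUR", "HIS"),
  n_samples = c(2000L, 2000L, 2000L),
  stringsAsFactors = FALSE)

N_VARIANTS <- 500L

# pinned frequencies/quality for the planted variants; all others drawn
MAFS <- rep(NA_real_, N_VARIANTS)
RSQS <- rep(NA_real_, N_VARIANTS)
MAFS[c(100L, 200L, 300L)] <- c(0.10, 0.30, 0.20)
RSQS[c(100L, 200L, 300L)] <- 0.95

EFFECTS <- data.frame(
  variant = c(100L, 200L, 300L),
  trait = c("SBP", "SBP", "DBP"),
  exposure = c("STST", "STST", "LTST"),
  beta_main = c(0, 1.5, 0),
  beta_gxe = c(-5, -0.9, -4))

cohort_sim_config <- function(i) {
  sim_config(n_samples = COHORTS$n_samples[i], n_variants = N_VARIANTS,
             maf = MAFS, rsq = RSQS,
             populations = COHORTS$population[i], divergence = 0.05,
             effect_table = EFFECTS, seed = SEED + 101L * i)
}

# the variant panel (positions, alleles, population frequencies) is shared
# across cohorts; population frequencies diverge by the Balding-Nichols draw
shared_panel <- function() {
  simulate_variant_panel(
    sim_config(n_samples = 100L, n_variants = N_VARIANTS, maf = MAFS,
               rsq = RSQS, populations = unique(COHORTS$population),
               divergence = 0.05, seed = SEED))
}

simulate_all_cohorts <- function() {
  panel <- shared_panel()
  setNames(lapply(seq_len(nrow(COHORTS)), function(i)
    simulate_cohort(cohort_sim_config(i), panel)), COHORTS$name)
}

harmonize_all <- function(raws = simulate_all_cohorts()) {
  lapply(raws, harmonize_cohort)
}
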