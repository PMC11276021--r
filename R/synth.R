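#' Simulation configuration for synthetic multi-population cohorts
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size, variant
#' panel, allele-frequency divergence across population groups, the total
#' sleep time (TST) generator, planted genetic main and gene-by-sleep
#' interaction effects, and phenotype noise.
#'
#' @param n_samples samples per cohort.
#' @param n_variants autosomal variants on the panel.
#' @param maf_range range of ancestral effect-allele frequencies; variants are
#'   drawn log-uniformly over it so the rare end (0.1--2\%) is represented.
#' @param populations character vector of population-group labels; samples are
#'   split equally across groups within a cohort.
#' @param divergence Balding--Nichols Fst-like divergence parameter in
#'   \[0, 0.5\]; 0 means all groups share the ancestral frequency.
#' @param exposure_model list with \code{mean}, \code{sd} (hours),
#'   \code{age_slope} (hours/year, centred at age 50) and \code{sex_offset}
#'   (hours added for females) of the TST generator.
#' @param effect_table data.frame with columns \code{variant} (1-based index),
#'   \code{trait} (SBP/DBP/PP), \code{exposure} (STST/LTST),
#'   \code{beta_main} and \code{beta_gxe} (mmHg per effect allele); planted
#'   effects on PP are added to SBP so that PP = SBP - DBP inherits them.
#' @param noise_sd residual phenotype noise in mmHg.
#' @param med_prevalence antihypertensive-medication prevalence.
#' @param n_readings BP readings per sample; \code{reading_sd} is the
#'   within-visit measurement noise in mmHg.
#' @param n_centers,n_pcs study centres and principal components carried as
#'   covariates.
#' @param maf optional vector of length \code{n_variants} overriding the
#'   ancestral frequency draw where non-NA (used to pin planted variants'
#'   frequencies).
#' @param rsq optional vector of length \code{n_variants} overriding the
#'   imputation-quality draw (used to pin planted variants' quality).
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 500,
                       maf_range = c(0.001, 0.5),
                       populations = "EUR", divergence = 0.05,
                       exposure_model = list(mean = 7.5, sd = 1.2,
                                             age_slope = -0.01,
                                             sex_offset = 0.2),
                       effect_table = NULL, noise_sd = 8,
                       med_prevalence = 0.15,
                       n_readings = 2, reading_sd = 2,
                       n_centers = 2, n_pcs = 2,
                       maf = NULL, rsq = NULL, seed = 1L) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair of frequencies in (0, 1)")
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (med_prevalence < 0 || med_prevalence > 1)
    stop("med_prevalence must be in [0, 1]")
  if (!is.null(effect_table)) {
    req <- c("variant", "trait", "exposure", "beta_main", "beta_gxe")
    if (!all(req %in% names(effect_table)))
      stop("effect_table needs columns: ", paste(req, collapse = ", "))
    if (any(effect_table$variant < 1 | effect_table$variant > n_variants))
      stop("effect_table variant indices must lie in [1, n_variants]")
    if (!all(effect_table$trait %in% c("SBP", "DBP", "PP")))
      stop("effect_table traits must be SBP, DBP or PP")
    if (!all(effect_table$exposure %in% c("STST", "LTST")))
      stop("effect_table exposures must be STST or LTST")
  }
  if (!is.null(maf) && length(maf) != n_variants)
    stop("maf override must have length n_variants")
  if (!is.null(rsq) && length(rsq) != n_variants)
    stop("rsq override must have length n_variants")
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, populations = populations,
                 divergence = divergence, exposure_model = exposure_model,
                 effect_table = effect_table, noise_sd = noise_sd,
                 med_prevalence = med_prevalence,
                 n_readings = as.integer(n_readings), reading_sd = reading_sd,
                 n_centers = as.integer(n_centers), n_pcs = as.integer(n_pcs),
                 maf = maf, rsq = rsq, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the shared variant panel
#'
#' Draws ancestral effect-allele frequencies over the configured MAF spectrum
#' and, per population group, a Balding--Nichols
#' Beta(p(1-F)/F, (1-p)(1-F)/F) frequency around the ancestral value. Variant
#' positions are laid out across autosomes 1--22 at 1 Mb spacing; each variant
#' carries a simulated imputation R-squared drawn Uniform(0.3, 1), used only
#' by downstream filters.
#'
#' @param config a \code{sim_config}.
#' @return data.frame with columns id, chrom, pos, ea, oa, af_ancestral,
#'   one \code{af_<group>} column per population group, and rsq.
#' @export
simulate_variant_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  lo <- log(config$maf_range[1]); hi <- log(config$maf_range[2])
  p0 <- exp(stats::runif(m, lo, hi))
  if (!is.null(config$maf)) {
    pin <- !is.na(config$maf)
    p0[pin] <- config$maf[pin]
  }
  chrom <- rep_len(1:22, m)
  pos <- integer(m)
  for (ch in 1:22) {
    idx <- which(chrom == ch)
    pos[idx] <- 1000000L * seq_along(idx)
  }
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), character(1))
  fst <- config$divergence
  af <- matrix(NA_real_, m, length(config$populations),
               dimnames = list(NULL, config$populations))
  for (k in seq_along(config$populations)) {
    if (fst == 0) {
      af[, k] <- p0
    } else {
      af[, k] <- stats::rbeta(m, p0 * (1 - fst) / fst,
                              (1 - p0) * (1 - fst) / fst)
      # keep drawn frequencies polymorphic
      af[, k] <- pmin(pmax(af[, k], 1e-4), 1 - 1e-4)
    }
  }
  out <- data.frame(id = sprintf("var%05d", seq_len(m)),
                    chrom = chrom, pos = pos, ea = ea, oa = oa,
                    af_ancestral = p0,
                    stringsAsFactors = FALSE)
  for (k in seq_along(config$populations))
    out[[paste0("af_", config$populations[k])]] <- af[, k]
  out$rsq <- stats::runif(m, 0.3, 1)
  if (!is.null(config$rsq)) {
    pin <- !is.na(config$rsq)
    out$rsq[pin] <- config$rsq[pin]
  }
  rownames(out) <- NULL
  out
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Samples are split equally across the configured population groups; each
#' sample's genotype at each variant is a Binomial(2, af_group) draw expressed
#' as a dosage in \[0, 2\]. Imputation R-squared does not perturb dosages; it
#' only feeds the degrees-of-freedom filter downstream.
#'
#' @param config a \code{sim_config}.
#' @param panel optional panel from \code{\link{simulate_variant_panel}};
#'   regenerated from \code{config} when missing. Passing a shared panel makes
#'   several cohorts draw from the same population frequencies.
#' @return list with \code{dosages} (variants x samples matrix),
#'   \code{variants} (panel plus a cohort \code{af} column of empirical
#'   frequencies), and \code{population} (per-sample group labels).
#' @export
simulate_genotypes <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) panel <- simulate_variant_panel(config)
  set.seed(config$seed + 1000L)
  n <- config$n_samples
  m <- config$n_variants
  pops <- rep_len(config$populations, n)
  G <- matrix(NA_real_, m, n)
  for (k in seq_along(config$populations)) {
    cols <- which(pops == config$populations[k])
    afk <- panel[[paste0("af_", config$populations[k])]]
    G[, cols] <- stats::rbinom(m * length(cols), 2L, rep(afk, length(cols)))
  }
  dimnames(G) <- list(panel$id, sprintf("S%05d", seq_len(n)))
  variants <- panel
  variants$af <- rowMeans(G) / 2
  list(dosages = G, variants = variants, population = pops)
}

# residual-percentile sleep exposure used both by the generator (truth) and
# by harmonization (re-derivation); kept here to guarantee the two agree.
.sleep_exposure_truth <- function(tst, age, sex) {
  derive_sleep_exposures(tst, age, sex)
}

#' Simulate phenotypes with planted genetic and interaction effects
#'
#' TST is Normal(mean + age_slope*(age-50) + sex_offset*sex, sd), truncated to
#' \[2, 15\] hours. BP traits are built from age, sex, centre and PC effects
#' plus the planted per-variant main and interaction contributions and
#' Gaussian noise; the interaction uses the residual-percentile exposure
#' indicator that harmonization later re-derives. Medicated samples
#' (Bernoulli draws) have their raw readings lowered by 15/10 mmHg (SBP/DBP),
#' the amounts the harmonization adjustment adds back. Multiple raw readings
#' per visit carry independent measurement noise.
#'
#' @param genotypes output of \code{\link{simulate_genotypes}}.
#' @param config the same \code{sim_config}.
#' @return a \code{raw_cohort}: list with \code{samples} (phenotype table),
#'   \code{dosages}, \code{variants}, and \code{truth} (one row per planted
#'   effect: variant id, trait, exposure, beta_main, beta_gxe).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  n <- config$n_samples
  G <- genotypes$dosages
  em <- config$exposure_model

  age <- stats::runif(n, 20, 80)
  sex <- stats::rbinom(n, 1L, 0.5)           # 0 = male, 1 = female
  center <- sample(seq_len(config$n_centers), n, replace = TRUE)
  pcs <- matrix(stats::rnorm(n * config$n_pcs, sd = 1), n, config$n_pcs)
  if (length(config$populations) > 1) {
    # population structure leaks into the leading PC, as in real data
    pcs[, 1] <- pcs[, 1] + 2 * (as.integer(factor(genotypes$population)) - 1)
  }
  colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))

  tst <- stats::rnorm(n, em$mean + em$age_slope * (age - 50) +
                        em$sex_offset * sex, em$sd)
  tst <- pmin(pmax(tst, 2), 15)
  expo <- .sleep_exposure_truth(tst, age, sex)

  sbp <- 120 + 0.45 * (age - 50) - 3 * sex + 0.5 * pcs[, 1] +
    0.8 * (center - 1) + stats::rnorm(n, sd = config$noise_sd)
  dbp <- 75 + 0.20 * (age - 50) - 2 * sex + 0.3 * pcs[, 1] +
    0.5 * (center - 1) + stats::rnorm(n, sd = config$noise_sd)

  truth <- NULL
  et <- config$effect_table
  if (!is.null(et) && nrow(et) > 0) {
    for (r in seq_len(nrow(et))) {
      g <- G[et$variant[r], ]
      if (stats::var(g) == 0)
        warning("planted effect on monomorphic variant ",
                genotypes$variants$id[et$variant[r]])
      e <- if (et$exposure[r] == "STST") expo$stst else expo$ltst
      contrib <- et$beta_main[r] * g + et$beta_gxe[r] * g * e
      # PP effects are planted through SBP so PP = SBP - DBP inherits them
      if (et$trait[r] == "DBP") dbp <- dbp + contrib else sbp <- sbp + contrib
    }
    truth <- data.frame(id = genotypes$variants$id[et$variant],
                        trait = et$trait, exposure = et$exposure,
                        beta_main = et$beta_main, beta_gxe = et$beta_gxe,
                        stringsAsFactors = FALSE)
  }

  med <- stats::rbinom(n, 1L, config$med_prevalence)
  samples <- data.frame(sample_id = colnames(G), age = age, sex = sex,
                        tst_hours = tst, stringsAsFactors = FALSE)
  for (j in seq_len(config$n_readings)) {
    samples[[paste0("sbp_", j)]] <- sbp - 15 * med +
      stats::rnorm(n, sd = config$reading_sd)
    samples[[paste0("dbp_", j)]] <- dbp - 10 * med +
      stats::rnorm(n, sd = config$reading_sd)
  }
  samples$med_bp <- med
  samples$center <- center
  samples <- cbind(samples, as.data.frame(pcs))
  samples$population <- genotypes$population

  structure(list(samples = samples, dosages = G,
                 variants = genotypes$variants, truth = truth,
                 config = config),
            class = "raw_cohort")
}

#' Simulate a complete synthetic cohort
#'
#' @param config a \code{sim_config}.
#' @param panel optional shared variant panel.
#' @return a \code{raw_cohort} (see \code{\link{simulate_phenotypes}}).
#' @export
simulate_cohort <- function(config, panel = NULL) {
  simulate_phenotypes(simulate_genotypes(config, panel), config)
}

#' Write a cohort to disk (VCF with DS genotypes + phenotype/truth TSVs)
#'
#' The VCF is v4.2 with a single FORMAT/DS field, contig header lines for all
#' chromosomes present, and AF/R2 INFO entries; dosages are serialized at six
#' decimals so read-back round-trips exactly at that precision.
#'
#' @param cohort a \code{raw_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raw_cohort"))
  if (is.null(cohort$samples) || nrow(cohort$samples) == 0 ||
      is.null(cohort$dosages) || nrow(cohort$dosages) == 0)
    stop("refusing to write an empty cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- cohort$variants
  meta <- c("##fileformat=VCFv4.2",
            "##source=gxesleep",
            paste0("##contig=<ID=", sort(unique(v$chrom)), ">"),
            paste0("##INFO=<ID=AF,Number=A,Type=Float,",
                   "Description=\"Effect allele frequency\">"),
            paste0("##INFO=<ID=R2,Number=1,Type=Float,",
                   "Description=\"Imputation quality\">"),
            paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                   "Description=\"Estimated alternate allele dosage\">"))
  fix <- cbind(CHROM = as.character(v$chrom), POS = as.character(v$pos),
               ID = v$id, REF = v$oa, ALT = v$ea, QUAL = ".", FILTER = "PASS",
               INFO = sprintf("AF=%.6g;R2=%.6g", v$af, v$rsq))
  gt <- cbind(FORMAT = "DS",
              matrix(sprintf("%.6f", cohort$dosages),
                     nrow = nrow(cohort$dosages),
                     dimnames = dimnames(cohort$dosages)))
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  paths <- c(vcf = file.path(dir, "cohort.vcf.gz"),
             pheno = file.path(dir, "pheno.tsv"),
             truth = file.path(dir, "truth.tsv"))
  vcfR::write.vcf(vcf, file = paths["vcf"])
  data.table::fwrite(cohort$samples, paths["pheno"], sep = "\t")
  truth <- cohort$truth
  if (is.null(truth))
    truth <- data.frame(id = character(), trait = character(),
                        exposure = character(), beta_main = numeric(),
                        beta_gxe = numeric())
  data.table::fwrite(truth, paths["truth"], sep = "\t")
  invisible(paths)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory holding cohort.vcf.gz, pheno.tsv and truth.tsv.
#' @return a \code{raw_cohort}.
#' @export
read_cohort <- function(dir) {
  vcf <- vcfR::read.vcfR(file.path(dir, "cohort.vcf.gz"), verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info <- fix$INFO
  af <- as.numeric(sub(".*AF=([^;]+).*", "\\1", info))
  rsq <- as.numeric(sub(".*R2=([^;]+).*", "\\1", info))
  variants <- data.frame(id = fix$ID, chrom = as.integer(fix$CHROM),
                         pos = as.integer(fix$POS), ea = fix$ALT,
                         oa = fix$REF, af = af, rsq = rsq,
                         stringsAsFactors = FALSE)
  rownames(ds) <- variants$id
  samples <- as.data.frame(data.table::fread(file.path(dir, "pheno.tsv")))
  tpath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tpath) && file.size(tpath) > 0)
    as.data.frame(data.table::fread(tpath)) else NULL
  if (!is.null(truth) && nrow(truth) == 0) truth <- NULL
  structure(list(samples = samples, dosages = ds, variants = variants,
                 truth = truth, config = NULL),
            class = "raw_cohort")
}
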