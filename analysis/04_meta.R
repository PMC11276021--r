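#!/usr/bin/env Rscript
# Stage 4: two-level meta-analysis. Cohort summary statistics are pooled
# within each population group (inverse-variance 1 df, joint 2 df with the
# pooled covariance) with genomic-control correction from the pooled
# statistics, then the group-level results are combined in the
# cross-population meta-analysis (CPMA) with a second GC pass.

source(file.path("analysis", "config.R"))

combos <- as.vector(outer(c("SBP", "DBP", "PP"),
                          outer(c("STST", "LTST"),
                                c("combined", "female", "male"),
                                paste, sep = "."),
                          paste, sep = "."))
lambda_log <- list()
for (key in combos) {
  by_group <- list()
  for (pg in unique(COHORTS$population)) {
    members <- COHORTS$name[COHORTS$population == pg]
    tl <- lapply(members, function(nm)
      read_summary_stats(file.path(RESULTS, "gwis", nm,
                                   paste0(key, ".tsv"))))
    names(tl) <- members
    mt <- population_meta(tl)
    by_group[[pg]] <- mt
    lambda_log[[paste(pg, key, sep = ".")]] <- attr(mt, "lambda_report")
    write_summary_stats(mt, file.path(RESULTS, "meta", pg,
                                      paste0(key, ".tsv")))
  }
  cp <- cross_population_meta(by_group)
  lambda_log[[paste("CPMA", key, sep = ".")]] <- attr(cp, "lambda_report")
  write_summary_stats(cp, file.path(RESULTS, "meta", "CPMA",
                                    paste0(key, ".tsv")))
}
jsonlite::write_json(lambda_log, file.path(RESULTS, "meta", "lambdas.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cp <- read_summary_stats(file.path(RESULTS, "meta", "CPMA",
                                   "SBP.STST.combined.tsv"))
top <- cp[which.min(cp$P_INT)]
cat(sprintf("CPMA SBP x STST: %d variants, top interaction %s beta %.2f (se %.2f), p %.2e over %d cohorts (N = %d)\n",
            nrow(cp), top$SNPID, top$BETA_INT, top$SE_INT, top$P_INT,
            top$K_COHORTS, top$N))
lam <- lambda_log[["CPMA.SBP.STST.combined"]]
cat(sprintf("CPMA lambdas (marg/main/int/joint): %.3f %.3f %.3f %.3f\n",
            lam$marg, lam$main, lam$int, lam$joint))
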