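#!/usr/bin/env Rscript
# Stage 3: per-cohort genome-wide interaction scan. Fits the interaction
# model M1 (trait ~ C1 + G + E.G) and marginal model M2 (trait ~ C2 + G)
# with HC0 robust covariance for every variant passing the MAF / imputation
# quality / MACxR2 filters, across all 18 trait x exposure x sex-group
# combinations, and writes one summary-statistics TSV per combination.

source(file.path("analysis", "config.R"))

hcs <- harmonize_all()

for (nm in names(hcs)) {
  tabs <- gwis_scan(hcs[[nm]])
  outdir <- file.path(RESULTS, "gwis", nm)
  for (key in names(tabs))
    write_summary_stats(tabs[[key]], file.path(outdir, paste0(key, ".tsv")))
  tb <- tabs[["SBP.STST.combined"]]
  hit <- tb[which.min(tb$P_INT)]
  cat(sprintf("%s: %d/%d variants pass filters; top SBP x STST interaction %s (beta %.2f, se %.2f, p %.2e)\n",
              nm, nrow(tb), N_VARIANTS, hit$SNPID, hit$BETA_INT, hit$SE_INT,
              hit$P_INT))
}
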