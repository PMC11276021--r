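#!/usr/bin/env Rscript
# Stage 2: apply the centralized harmonization protocol to each cohort --
# averaging repeated readings, +15/+10 mmHg medication adjustment, pulse
# pressure derivation, 6-SD winsorization, age/sleep-window/complete-case
# filters, and residual-percentile STST/LTST exposures. Writes one
# analysis-ready phenotype TSV per cohort plus a JSON sidecar with the
# per-filter sample counts.

source(file.path("analysis", "config.R"))

hcs <- harmonize_all()

counts <- list()
for (nm in names(hcs)) {
  hc <- hcs[[nm]]
  out <- file.path(RESULTS, "harmonized", paste0(nm, ".tsv"))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(hc$pheno, out, sep = "\t")
  counts[[nm]] <- c(list(kept = nrow(hc$pheno)), as.list(hc$drop_counts))
  cat(sprintf("%s: kept %d samples (dropped: age %d, sleep window %d, missing %d); STST %.1f%%, LTST %.1f%%\n",
              nm, nrow(hc$pheno), hc$drop_counts["age"],
              hc$drop_counts["tst"], hc$drop_counts["missing"],
              100 * mean(hc$pheno$stst), 100 * mean(hc$pheno$ltst)))
}
jsonlite::write_json(counts, file.path(RESULTS, "harmonized", "counts.json"),
                     auto_unbox = TRUE, pretty = TRUE)
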