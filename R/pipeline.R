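.SUMSTAT_COLS <- c("SNPID", "CHR", "POS", "EA", "OA", "EAF", "N",
                   "BETA_MARG", "SE_MARG", "BETA_MAIN", "SE_MAIN",
                   "BETA_INT", "SE_INT", "COV_MAIN_INT",
                   "P_MARG", "P_MAIN", "P_INT", "P_JOINT")

#' Write a summary-statistics table to TSV
#'
#' @param rows data.frame/data.table of per-variant statistics.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_summary_stats <- function(rows, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(rows), path, sep = "\t")
  invisible(path)
}

#' Read a summary-statistics TSV with validation
#'
#' Rows with missing or invalid values (SE <= 0, p outside (0, 1\], EAF
#' outside (0, 1)) and duplicated SNPIDs are dropped; the counts are
#' recorded in a \code{dropped} attribute. Unknown columns produce a
#' warning; missing required columns are an error.
#'
#' @param path TSV path.
#' @return data.table with a \code{dropped} attribute.
#' @export
read_summary_stats <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  miss <- setdiff(.SUMSTAT_COLS, names(tab))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  extra_known <- c("DF_TOT", "DF_EXP", "DF_UNEXP", "K_COHORTS", "DIRECTIONS",
                   "BETA_MAIN_2DF", "BETA_INT_2DF", "SE_MAIN_2DF",
                   "SE_INT_2DF", "CHISQ_JOINT", "PALINDROMIC")
  unknown <- setdiff(names(tab), c(.SUMSTAT_COLS, extra_known))
  if (length(unknown) > 0)
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
  n0 <- nrow(tab)
  core <- .SUMSTAT_COLS
  ok <- stats::complete.cases(tab[, core, with = FALSE])
  for (sc in c("SE_MARG", "SE_MAIN", "SE_INT"))
    ok <- ok & tab[[sc]] > 0
  for (pc in c("P_MARG", "P_MAIN", "P_INT", "P_JOINT"))
    ok <- ok & tab[[pc]] > 0 & tab[[pc]] <= 1
  ok <- ok & tab$EAF > 0 & tab$EAF < 1
  ok[is.na(ok)] <- FALSE
  n_invalid <- sum(!ok)
  tab <- tab[ok]
  dup <- duplicated(tab$SNPID)
  n_dup <- sum(dup)
  if (n_dup > 0) message(n_dup, " duplicated SNPID row(s) dropped")
  tab <- tab[!dup]
  attr(tab, "dropped") <- c(invalid = n_invalid, duplicate = n_dup,
                            kept = nrow(tab), input = n0)
  tab
}

#' Build a pipeline run configuration
#'
#' A run is defined by a cohort manifest (name, population group, size), the
#' simulation, filter and significance settings, the robust-covariance
#' flavour, and a master seed. Cohort-level seeds are derived
#' deterministically from the master seed, so a stored configuration
#' reproduces a run exactly.
#'
#' @param cohorts data.frame with columns name, population, n_samples.
#' @param n_variants shared variant-panel size.
#' @param sim named list of overrides passed to \code{\link{sim_config}}.
#' @param traits,exposures,sex_groups analysis combinations.
#' @param robust robust covariance flavour.
#' @param filter a \code{\link{filter_config}}.
#' @param significance a \code{\link{significance_config}}.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a \code{run_config} list.
#' @export
run_config <- function(cohorts, n_variants = 500, sim = list(),
                       traits = c("SBP", "DBP", "PP"),
                       exposures = c("STST", "LTST"),
                       sex_groups = c("combined", "female", "male"),
                       robust = "HC0", filter = filter_config(),
                       significance = significance_config(),
                       seed = 1L, out_dir = tempfile("gxesleep_run")) {
  structure(list(cohorts = cohorts, n_variants = n_variants, sim = sim,
                 traits = traits, exposures = exposures,
                 sex_groups = sex_groups, robust = robust, filter = filter,
                 significance = significance, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a \code{run_config} (or a plain list from YAML).
#' @return data.frame of issues (severity, message); zero fatal rows means
#'   the configuration is runnable.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(sev, msg) issues[[length(issues) + 1]] <<-
    data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
  if (is.null(config$cohorts) || nrow(config$cohorts) == 0)
    add("fatal", "cohort manifest is empty")
  else {
    req <- c("name", "population", "n_samples")
    miss <- setdiff(req, names(config$cohorts))
    if (length(miss) > 0)
      add("fatal", paste("cohort manifest missing columns:",
                         paste(miss, collapse = ", ")))
    else if (any(config$cohorts$n_samples < 50))
      add("fatal", "cohort n_samples must be >= 50")
  }
  if (!is.null(config$n_variants) && config$n_variants < 1)
    add("fatal", "n_variants must be >= 1")
  if (!config$robust %in% c("HC0", "HC1", "HC3"))
    add("fatal", paste0("unknown robust estimator '", config$robust,
                        "'; valid options: HC0, HC1, HC3"))
  for (thr in c("maf_min", "rsq_min", "df_min"))
    if (!is.null(config$filter[[thr]]) && config$filter[[thr]] <= 0)
      add("fatal", paste(thr, "must be positive"))
  if (length(issues) == 0)
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Read / write a run configuration as YAML
#'
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @return \code{read_run_config} returns a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  plain <- config
  plain$cohorts <- as.list(as.data.frame(config$cohorts))
  plain$filter <- unclass(config$filter)
  plain$significance <- unclass(config$significance)
  yaml::write_yaml(unclass(plain), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$cohorts <- as.data.frame(y$cohorts, stringsAsFactors = FALSE)
  y$filter <- do.call(filter_config, y$filter)
  y$significance <- do.call(significance_config, y$significance)
  class(y) <- "run_config"
  y
}

#' Run the full pipeline: simulate, harmonize, scan, meta-analyze, discover
#'
#' Executes, per cohort: synthetic-cohort simulation from a shared variant
#' panel, harmonization and the genome-wide interaction scan; then a
#' population-group meta-analysis per group, a cross-population
#' meta-analysis, and locus discovery per analysis combination. All outputs
#' are written under \code{config$out_dir} alongside a manifest JSON with
#' MD5 checksums and a counts log, so identical configurations yield
#' identical checksums.
#'
#' @param config a \code{run_config}.
#' @param known_bp_loci,known_gxe_loci optional known-locus tables
#'   (chrom, pos) for novelty annotation.
#' @return list with \code{cohort_tables}, \code{group_meta}, \code{cpma},
#'   \code{loci}, \code{lambda_reports}, \code{counts}, \code{manifest}.
#' @export
run_pipeline <- function(config, known_bp_loci = NULL,
                         known_gxe_loci = NULL) {
  issues <- validate_config(config)
  if (any(issues$severity == "fatal"))
    stop("invalid configuration:\n  ",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  combos <- expand.grid(trait = config$traits, exposure = config$exposures,
                        sex = config$sex_groups, stringsAsFactors = FALSE)
  counts <- list()

  pops <- unique(config$cohorts$population)
  panel_cfg <- do.call(sim_config, utils::modifyList(
    list(n_samples = 100L, n_variants = config$n_variants,
         populations = pops, seed = config$seed), config$sim))
  panel <- simulate_variant_panel(panel_cfg)

  cohort_tables <- list()
  cohort_dosages <- list()
  for (i in seq_len(nrow(config$cohorts))) {
    cname <- config$cohorts$name[i]
    ccfg <- do.call(sim_config, utils::modifyList(
      list(n_samples = config$cohorts$n_samples[i],
           n_variants = config$n_variants,
           populations = config$cohorts$population[i],
           seed = config$seed + 101L * i), config$sim))
    raw <- simulate_cohort(ccfg, panel)
    hc <- harmonize_cohort(raw)
    counts[[cname]] <- list(simulated = nrow(raw$samples),
                            kept = nrow(hc$pheno),
                            dropped = as.list(hc$drop_counts))
    tabs <- gwis_scan(hc, config$traits, config$exposures,
                      config$sex_groups, config$filter, config$robust)
    cdir <- file.path(config$out_dir, "cohorts", cname)
    for (nm in names(tabs))
      write_summary_stats(tabs[[nm]], file.path(cdir, paste0(nm, ".tsv")))
    cohort_tables[[cname]] <- tabs
    cohort_dosages[[cname]] <- hc$dosages
  }
  all_dosages <- do.call(cbind, cohort_dosages)

  group_meta <- list()
  lambda_reports <- list()
  for (pg in pops) {
    members <- config$cohorts$name[config$cohorts$population == pg]
    for (ci in seq_len(nrow(combos))) {
      key <- paste(combos$trait[ci], combos$exposure[ci], combos$sex[ci],
                   sep = ".")
      tl <- lapply(cohort_tables[members], `[[`, key)
      tl <- tl[vapply(tl, nrow, integer(1)) > 0]
      if (length(tl) == 0) next
      mt <- population_meta(tl)
      group_meta[[pg]][[key]] <- mt
      lambda_reports[[paste(pg, key, sep = ".")]] <-
        attr(mt, "lambda_report")
      write_summary_stats(mt, file.path(config$out_dir, "meta", pg,
                                        paste0(key, ".tsv")))
    }
  }

  cpma <- list()
  for (ci in seq_len(nrow(combos))) {
    key <- paste(combos$trait[ci], combos$exposure[ci], combos$sex[ci],
                 sep = ".")
    gl <- lapply(group_meta, `[[`, key)
    gl <- gl[!vapply(gl, is.null, logical(1))]
    if (length(gl) == 0) next
    ct <- cross_population_meta(gl)
    cpma[[key]] <- ct
    lambda_reports[[paste("CPMA", key, sep = ".")]] <-
      attr(ct, "lambda_report")
    write_summary_stats(ct, file.path(config$out_dir, "meta", "CPMA",
                                      paste0(key, ".tsv")))
  }

  loci <- list()
  for (ci in which(combos$sex == "combined")) {
    tr <- combos$trait[ci]; ex <- combos$exposure[ci]
    key <- paste(tr, ex, "combined", sep = ".")
    if (is.null(cpma[[key]])) next
    loci[[key]] <- discover_loci(
      cpma[[key]], dosages = all_dosages, config = config$significance,
      known_bp_loci = known_bp_loci, known_gxe_loci = known_gxe_loci,
      female = cpma[[paste(tr, ex, "female", sep = ".")]],
      male = cpma[[paste(tr, ex, "male", sep = ".")]],
      trait = tr, exposure = ex, sex_group = "combined",
      population = "CPMA")
  }
  locus_report <- do.call(rbind, loci)
  if (!is.null(locus_report) && nrow(locus_report) > 0)
    data.table::fwrite(locus_report,
                       file.path(config$out_dir, "loci.tsv"), sep = "\t")

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = config$seed, files = manifest,
                            counts = counts),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort_tables = cohort_tables, group_meta = group_meta,
                 cpma = cpma, loci = locus_report,
                 lambda_reports = lambda_reports, counts = counts,
                 manifest = manifest))
}
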