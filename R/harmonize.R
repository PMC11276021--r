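#' Average repeated blood-pressure readings within a visit
#'
#' @param readings numeric matrix or data.frame, one row per sample, one
#'   column per reading. A sample with no non-missing reading yields NA and
#'   is excluded later by the complete-case rule.
#' @return numeric vector of per-sample means.
#' @export
average_bp_readings <- function(readings) {
  readings <- as.matrix(readings)
  out <- rowMeans(readings)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Adjust blood pressure for antihypertensive medication use
#'
#' Medicated samples get +15 mmHg added to SBP and +10 mmHg to DBP;
#' unmedicated samples are unchanged. A missing flag propagates NA so the
#' complete-case filter removes the sample.
#'
#' @param sbp,dbp numeric vectors (mmHg).
#' @param med 0/1 medication flag.
#' @return list with adjusted \code{sbp} and \code{dbp}.
#' @export
adjust_medication <- function(sbp, dbp, med) {
  list(sbp = sbp + 15 * med, dbp = dbp + 10 * med)
}

#' Derive pulse pressure
#'
#' @param sbp,dbp medication-adjusted SBP and DBP (mmHg).
#' @return PP = SBP - DBP.
#' @export
derive_pp <- function(sbp, dbp) sbp - dbp

#' Winsorize a trait at k standard deviations from the mean
#'
#' Single pass: the mean and SD are computed once on the input vector and the
#' values clamped to \[mean - k sd, mean + k sd\]. Ranks of order statistics
#' are preserved.
#'
#' @param x numeric vector.
#' @param k clamp width in SDs (default 6).
#' @return clamped vector.
#' @export
winsorize <- function(x, k = 6) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("constant vector: winsorization is a no-op")
    return(x)
  }
  m <- mean(x, na.rm = TRUE)
  pmin(pmax(x, m - k * s), m + k * s)
}

#' Sample-level inclusion filter
#'
#' Keeps samples with age >= 18 years, total sleep time within \[3, 14\]
#' hours (inclusive), and no missing value in any analysis field
#' (complete-case rule). Purely a subset operation: values are never
#' modified.
#'
#' @param samples data.frame holding at least \code{age} and
#'   \code{tst_hours}; all columns in \code{required} are checked for
#'   missingness.
#' @param required column names subject to the complete-case rule (default:
#'   all columns).
#' @return logical keep vector with a \code{drop_counts} attribute recording
#'   how many samples each rule removed.
#' @export
filter_samples <- function(samples, required = names(samples)) {
  ok_age <- !is.na(samples$age) & samples$age >= 18
  ok_tst <- !is.na(samples$tst_hours) & samples$tst_hours >= 3 &
    samples$tst_hours <= 14
  ok_cc <- stats::complete.cases(samples[, required, drop = FALSE])
  keep <- ok_age & ok_tst & ok_cc
  if (!any(keep)) stop("no samples left after harmonization filters")
  # disjoint attribution so that input - dropped = kept always balances
  attr(keep, "drop_counts") <- c(age = sum(!ok_age),
                                 tst = sum(ok_age & !ok_tst),
                                 missing = sum(ok_age & ok_tst & !ok_cc))
  keep
}

#' Derive short/long sleep exposure indicators
#'
#' Regresses TST on age, sex and age x sex; the residuals' 20th and 80th
#' percentiles are the cutoffs: STST = 1 iff residual <= 20th percentile,
#' LTST = 1 iff residual >= 80th percentile (ties at a cutoff are exposed).
#' In a single-sex sample the sex and age x sex terms are dropped.
#'
#' @param tst total sleep time in hours (filtered samples).
#' @param age age in years.
#' @param sex 0 = male, 1 = female.
#' @return list with integer vectors \code{stst} and \code{ltst} plus the
#'   residuals and cutoffs used.
#' @export
derive_sleep_exposures <- function(tst, age, sex) {
  n <- length(tst)
  if (n < 25) stop("need at least 25 samples to derive sleep exposures")
  X <- if (stats::var(sex) == 0) cbind(1, age)
       else cbind(1, age, sex, age * sex)
  r <- stats::lm.fit(X, tst)$residuals
  q <- stats::quantile(r, c(0.2, 0.8), names = FALSE, type = 7)
  list(stst = as.integer(r <= q[1]), ltst = as.integer(r >= q[2]),
       residuals = r, cutoffs = q)
}

#' Build the interaction (C1) and reduced (C2) design matrices
#'
#' C1 columns: intercept, E, age, age^2, sex, age x E, age^2 x E, sex x E,
#' principal components, centre dummies (treatment coding). C2 drops every
#' E-bearing column: intercept, age, age^2, sex, PCs, centre dummies.
#' Sex and sex x E are omitted in sex-stratified runs.
#'
#' @param df data.frame with age, sex, center and pc columns.
#' @param E 0/1 exposure vector aligned with \code{df}.
#' @param sex_group one of "combined", "female", "male".
#' @param pc_cols names of the PC columns (default: all starting "pc").
#' @return list with matrices \code{C1} and \code{C2}.
#' @export
build_designs <- function(df, E, sex_group = "combined",
                          pc_cols = grep("^pc", names(df), value = TRUE)) {
  if (stats::var(E) == 0) stop("exposure has no variance in this stratum")
  age <- df$age
  stratified <- sex_group != "combined"
  pcs <- as.matrix(df[, pc_cols, drop = FALSE])
  centers <- if (length(unique(df$center)) > 1) {
    cm <- stats::model.matrix(~ factor(center), df)[, -1, drop = FALSE]
    colnames(cm) <- paste0("center", seq_len(ncol(cm)) + 1)
    cm
  } else NULL
  C1 <- cbind(intercept = 1, E = E, age = age, age2 = age^2)
  if (!stratified) C1 <- cbind(C1, sex = df$sex)
  C1 <- cbind(C1, ageE = age * E, age2E = age^2 * E)
  if (!stratified) C1 <- cbind(C1, sexE = df$sex * E)
  C1 <- cbind(C1, pcs, centers)
  C2 <- cbind(intercept = 1, age = age, age2 = age^2)
  if (!stratified) C2 <- cbind(C2, sex = df$sex)
  C2 <- cbind(C2, pcs, centers)
  for (nm in c("C1", "C2")) {
    X <- get(nm)
    qd <- qr(X)
    if (qd$rank < ncol(X)) {
      bad <- colnames(X)[setdiff(seq_len(ncol(X)), qd$pivot[seq_len(qd$rank)])]
      stop(nm, " design is rank deficient; collinear columns: ",
           paste(bad, collapse = ", "))
    }
  }
  list(C1 = C1, C2 = C2)
}

#' Harmonize a raw cohort into analysis-ready traits and exposures
#'
#' Applies the centralized protocol: average repeated readings, adjust for
#' medication (+15/+10 mmHg), derive PP = SBP - DBP from adjusted values,
#' filter samples (age >= 18, TST in \[3, 14\], complete cases), winsorize
#' each trait at 6 SD on the analysis sample, and derive the STST/LTST
#' residual-percentile exposures once on the combined filtered sample.
#'
#' @param raw a \code{raw_cohort}.
#' @return a \code{harmonized_cohort}: list with \code{pheno} (id, age, sex,
#'   center, PCs, sbp, dbp, pp, stst, ltst), \code{dosages} restricted to
#'   kept samples, \code{variants}, and \code{drop_counts}.
#' @export
harmonize_cohort <- function(raw) {
  stopifnot(inherits(raw, "raw_cohort"))
  s <- raw$samples
  sbp_cols <- grep("^sbp_", names(s), value = TRUE)
  dbp_cols <- grep("^dbp_", names(s), value = TRUE)
  if (length(sbp_cols) == 0) { sbp_cols <- "sbp_raw"; dbp_cols <- "dbp_raw" }
  sbp <- average_bp_readings(s[, sbp_cols, drop = FALSE])
  dbp <- average_bp_readings(s[, dbp_cols, drop = FALSE])
  adj <- adjust_medication(sbp, dbp, s$med_bp)
  pp <- derive_pp(adj$sbp, adj$dbp)

  pc_cols <- grep("^pc", names(s), value = TRUE)
  core <- data.frame(sample_id = s$sample_id, age = s$age, sex = s$sex,
                     tst_hours = s$tst_hours, med_bp = s$med_bp,
                     center = s$center, s[, pc_cols, drop = FALSE],
                     sbp = adj$sbp, dbp = adj$dbp, pp = pp,
                     stringsAsFactors = FALSE)
  keep <- filter_samples(core)
  ph <- core[keep, , drop = FALSE]
  for (tr in c("sbp", "dbp", "pp")) ph[[tr]] <- winsorize(ph[[tr]])
  ex <- derive_sleep_exposures(ph$tst_hours, ph$age, ph$sex)
  ph$stst <- ex$stst
  ph$ltst <- ex$ltst
  rownames(ph) <- NULL
  structure(list(pheno = ph,
                 dosages = raw$dosages[, keep, drop = FALSE],
                 variants = raw$variants,
                 drop_counts = attr(keep, "drop_counts")),
            class = "harmonized_cohort")
}
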