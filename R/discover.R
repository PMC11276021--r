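#' Significance and locus-definition configuration
#'
#' @param p_gw genome-wide significance threshold (default 5e-9).
#' @param fdr_max Benjamini-Hochberg FDR ceiling (default 0.05).
#' @param p_screen marginal-effect screening threshold of the two-step
#'   method (default 1e-5).
#' @param region_kb physical clumping radius around a lead variant in kb
#'   (default 500).
#' @param ld_r2_max LD r-squared above which two lead variants are not
#'   independent (default 0.1).
#' @param novelty_mb distance in Mb to a known locus below which a hit is
#'   not novel (default 1).
#' @param n_min,k_cohorts_min meta-analysis eligibility: pooled N strictly
#'   above \code{n_min} (20000) or at least \code{k_cohorts_min} (3)
#'   contributing cohorts.
#' @param pca_var_explained variance fraction defining the effective number
#'   of tests (simpleM convention, default 0.995).
#' @return a \code{significance_config}.
#' @export
significance_config <- function(p_gw = 5e-9, fdr_max = 0.05,
                                p_screen = 1e-5, region_kb = 500,
                                ld_r2_max = 0.1, novelty_mb = 1,
                                n_min = 20000, k_cohorts_min = 3,
                                pca_var_explained = 0.995) {
  stopifnot(p_gw > 0, fdr_max > 0, p_screen > 0, region_kb > 0,
            ld_r2_max > 0, novelty_mb > 0, n_min > 0, k_cohorts_min > 0,
            pca_var_explained > 0, pca_var_explained <= 1)
  structure(as.list(environment()), class = "significance_config")
}

#' Meta-analysis eligibility for locus discovery
#'
#' @param tab meta table with N and K_COHORTS columns.
#' @param config a \code{\link{significance_config}}.
#' @return TRUE iff pooled N > n_min (strict) or K_COHORTS >= k_cohorts_min.
#' @export
eligibility <- function(tab, config = significance_config()) {
  if (nrow(tab) == 0) return(FALSE)
  max(tab$N) > config$n_min || max(tab$K_COHORTS) >= config$k_cohorts_min
}

# GRCh38 MHC interval used for masking
.MHC_HG38 <- c(start = 28510120, end = 33480577)

#' Exclude variants within 1 Mb of the MHC region
#'
#' The major histocompatibility complex is masked as chr6:28,510,120 -
#' 33,480,577 (GRCh38) with a 1 Mb buffer on each side.
#'
#' @param tab table with CHR and POS columns (hg38, 1-based).
#' @param buffer_bp buffer size (default 1e6).
#' @return filtered table.
#' @export
exclude_mhc <- function(tab, buffer_bp = 1e6) {
  drop <- tab$CHR == 6 & tab$POS >= .MHC_HG38["start"] - buffer_bp &
    tab$POS <= .MHC_HG38["end"] + buffer_bp
  tab[!drop, , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' @param p vector of p-values in (0, 1\].
#' @return monotone step-up q-values (empty input gives empty output).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Select variants significant by the 1 df interaction test (class i)
#'
#' @param tab meta table carrying P_INT and Q_INT (FDR over all scanned
#'   variants of the analysis).
#' @param config a \code{\link{significance_config}}.
#' @return subset of \code{tab}.
#' @export
select_1df <- function(tab, config = significance_config()) {
  tab[tab$P_INT < config$p_gw & tab$Q_INT < config$fdr_max, , drop = FALSE]
}

#' Select variants significant by the 2 df joint test (class j)
#'
#' @inheritParams select_1df
#' @return subset of \code{tab} with P_JOINT/Q_JOINT passing; independent of
#'   the 1 df selection.
#' @export
select_2df <- function(tab, config = significance_config()) {
  tab[tab$P_JOINT < config$p_gw & tab$Q_JOINT < config$fdr_max, ,
      drop = FALSE]
}

#' Effective number of independent tests among screened variants
#'
#' Eigen-decomposes the correlation matrix of the screened variants'
#' dosages; the effective count is the smallest k whose top-k eigenvalues
#' sum to at least \code{pca_var_explained} times the matrix dimension
#' (simpleM convention).
#'
#' @param dosages variants x samples dosage matrix of the screened set.
#' @param var_explained variance fraction (default 0.995).
#' @return integer between 1 and the number of variants.
#' @export
effective_tests <- function(dosages, var_explained = 0.995) {
  z <- nrow(dosages)
  if (z == 0) stop("no screened variants")
  if (z == 1) return(1L)
  C <- suppressWarnings(stats::cor(t(dosages)))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) >= var_explained * z)[1])
}

#' Two-step interaction screening (class k)
#'
#' Step 1 screens variants on the marginal effect (P_M2_G < p_screen);
#' step 2 keeps screened variants whose interaction p is below
#' 0.05 / N_G (N_G from \code{\link{effective_tests}}) and whose BH FDR,
#' computed within the screened set, is below fdr_max.
#'
#' @param tab meta table with P_MARG and P_INT.
#' @param dosages dosage matrix indexed by variant id (rownames) for the
#'   PCA step; screened variants missing from it are assumed independent.
#' @param config a \code{\link{significance_config}}.
#' @return subset of \code{tab} with attached N_G attribute.
#' @export
two_step <- function(tab, dosages = NULL, config = significance_config()) {
  screened <- tab[tab$P_MARG < config$p_screen, , drop = FALSE]
  z <- nrow(screened)
  if (z == 0) {
    out <- tab[0, , drop = FALSE]
    attr(out, "N_G") <- 0L
    return(out)
  }
  ng <- z
  if (!is.null(dosages)) {
    have <- intersect(screened$SNPID, rownames(dosages))
    if (length(have) >= 2) {
      ng <- effective_tests(dosages[have, , drop = FALSE],
                            config$pca_var_explained)
      ng <- ng + (z - length(have))      # unseen variants count as independent
    } else ng <- z
  }
  q <- bh_fdr(screened$P_INT)
  keep <- screened$P_INT < 0.05 / ng & q < config$fdr_max
  out <- screened[keep, , drop = FALSE]
  attr(out, "N_G") <- as.integer(ng)
  out
}

#' LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation; allele flips (g -> 2 - g) leave it
#' unchanged. A constant vector has undefined correlation and is treated as
#' r^2 = 0 with a warning.
#'
#' @param g1,g2 equal-length dosage vectors.
#' @return scalar r-squared.
#' @export
ld_r2 <- function(g1, g2) {
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    warning("constant dosage vector: r^2 treated as 0")
    return(0)
  }
  stats::cor(g1, g2)^2
}

#' Clump significant variants into loci
#'
#' Greedy: the most significant unassigned variant becomes a lead; every
#' unassigned significant variant within the physical radius on the same
#' chromosome joins its locus; repeat. Loci whose leads are in LD
#' (r^2 >= ld_r2_max) are then merged into the stronger locus. Ties on p are
#' broken by larger absolute beta, then lower position. The result is
#' invariant to input row order.
#'
#' @param sig data.frame with SNPID, CHR, POS, P (route-specific p) and BETA
#'   (tie-break magnitude).
#' @param dosages optional dosage matrix (rownames = SNPID) supplying LD;
#'   leads missing from it fall back to physical separation only.
#' @param config a \code{\link{significance_config}}.
#' @return data.frame of loci: LEAD_SNP, CHR, POS, P, N_MEMBERS, MEMBERS
#'   (comma-separated ids).
#' @export
clump <- function(sig, dosages = NULL, config = significance_config()) {
  if (nrow(sig) == 0)
    return(data.frame(LEAD_SNP = character(), CHR = integer(),
                      POS = integer(), P = numeric(), N_MEMBERS = integer(),
                      MEMBERS = character(), stringsAsFactors = FALSE))
  sig <- sig[order(sig$P, -abs(sig$BETA), sig$POS, sig$SNPID), , drop = FALSE]
  radius <- config$region_kb * 1000
  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  while (!all(assigned)) {
    lead <- which(!assigned)[1]
    memb <- which(!assigned & sig$CHR == sig$CHR[lead] &
                    abs(sig$POS - sig$POS[lead]) <= radius)
    assigned[memb] <- TRUE
    loci[[length(loci) + 1]] <-
      list(lead = lead, members = sig$SNPID[memb])
  }
  # merge loci with dependent leads (LD r^2 >= threshold) into the stronger
  if (!is.null(dosages) && length(loci) > 1) {
    keep <- rep(TRUE, length(loci))
    for (i in seq_along(loci)) {
      if (!keep[i]) next
      for (j in seq_along(loci)) {
        if (j <= i || !keep[j]) next
        li <- sig$SNPID[loci[[i]]$lead]; lj <- sig$SNPID[loci[[j]]$lead]
        if (!(li %in% rownames(dosages)) || !(lj %in% rownames(dosages)))
          next
        r2 <- suppressWarnings(ld_r2(dosages[li, ], dosages[lj, ]))
        if (r2 >= config$ld_r2_max) {
          loci[[i]]$members <- union(loci[[i]]$members, loci[[j]]$members)
          keep[j] <- FALSE
        }
      }
    }
    loci <- loci[keep]
  }
  do.call(rbind, lapply(loci, function(l) {
    data.frame(LEAD_SNP = sig$SNPID[l$lead], CHR = sig$CHR[l$lead],
               POS = sig$POS[l$lead], P = sig$P[l$lead],
               N_MEMBERS = length(l$members),
               MEMBERS = paste(sort(l$members), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

.near_known <- function(chr, pos, known, mb) {
  if (is.null(known) || nrow(known) == 0) return(NA)
  any(known$chrom == chr & abs(known$pos - pos) <= mb * 1e6)
}

#' Classify a locus: route, interaction-driven status, novelty
#'
#' 1 df / two-step loci form class X when farther than the novelty distance
#' from known gene-sleep interaction loci. 2 df loci enter prioritization
#' only when their marginal effect is insignificant (P_MARG > p_gw and
#' Q_MARG > fdr_max) and they are farther than the novelty distance from
#' known BP loci; they are class Y (driven) when P_INT < P_MAIN and class Z
#' (supported) otherwise. Without a known-loci table, novelty is unknown and
#' the locus is not called novel.
#'
#' @param lead_row one-row data.frame with P_INT, P_MAIN, P_MARG, Q_MARG,
#'   CHR, POS.
#' @param route "1df", "two-step" or "2df".
#' @param known_bp,known_gxe data.frames (chrom, pos) of known BP and known
#'   gene-sleep loci, or NULL.
#' @param config a \code{\link{significance_config}}.
#' @return list with \code{class} ("X", "Y", "Z" or NA), \code{driven},
#'   \code{novel_bp}, \code{prioritized}.
#' @export
classify_locus <- function(lead_row, route, known_bp = NULL,
                           known_gxe = NULL,
                           config = significance_config()) {
  near_bp <- .near_known(lead_row$CHR, lead_row$POS, known_bp,
                         config$novelty_mb)
  near_gxe <- .near_known(lead_row$CHR, lead_row$POS, known_gxe,
                          config$novelty_mb)
  novel_bp <- if (is.na(near_bp)) NA else !near_bp
  driven <- lead_row$P_INT < lead_row$P_MAIN
  if (route %in% c("1df", "two-step")) {
    cls <- if (isTRUE(near_gxe)) NA_character_ else "X"
    return(list(class = cls, driven = driven, novel_bp = novel_bp,
                prioritized = !isTRUE(near_gxe)))
  }
  marg_insig <- lead_row$P_MARG > config$p_gw &&
    lead_row$Q_MARG > config$fdr_max
  prioritized <- marg_insig && !isTRUE(near_bp)
  cls <- if (!prioritized) NA_character_ else if (driven) "Y" else "Z"
  list(class = cls, driven = driven, novel_bp = novel_bp,
       prioritized = prioritized)
}

#' Two-sample Z-test for sex heterogeneity of an interaction effect
#'
#' Z = (betaF - betaM) / sqrt(seF^2 + seM^2), two-sided normal p,
#' Bonferroni-significant when p < 0.05 / Q. A missing estimate in either
#' sex yields NA.
#'
#' @param betaF,seF,betaM,seM female and male estimates; vectorized.
#' @param Q number of loci tested.
#' @return data.frame with Z, P and SIGNIFICANT.
#' @export
sex_heterogeneity <- function(betaF, seF, betaM, seM, Q) {
  z <- (betaF - betaM) / sqrt(seF^2 + seM^2)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(Z = z, P = p, SIGNIFICANT = p < 0.05 / Q)
}

#' Discover and prioritize interaction loci from one meta-analysis
#'
#' Applies eligibility, MHC masking, FDR computation, the three significance
#' routes (1 df interaction, 2 df joint, two-step screening), clumping with
#' LD pruning, locus classification (X/Y/Z, interaction-driven, novelty) and
#' the sex-heterogeneity test when sex-stratified tables are supplied.
#'
#' @param meta GC-corrected meta table for one analysis.
#' @param dosages optional dosage matrix for LD and the two-step PCA.
#' @param config a \code{\link{significance_config}}.
#' @param known_bp_loci,known_gxe_loci data.frames (chrom, pos) or NULL.
#' @param female,male optional sex-stratified meta tables for the
#'   heterogeneity test.
#' @param trait,exposure,sex_group,population labels stamped on the output.
#' @return locus report data.frame.
#' @export
discover_loci <- function(meta, dosages = NULL,
                          config = significance_config(),
                          known_bp_loci = NULL, known_gxe_loci = NULL,
                          female = NULL, male = NULL,
                          trait = NA, exposure = NA, sex_group = NA,
                          population = NA) {
  empty <- data.frame(LOCUS_ID = character(), LEAD_SNP = character(),
                      CHR = integer(), POS = integer(), ROUTE = character(),
                      EXPOSURE = character(), TRAIT = character(),
                      SEX = character(), POP = character(),
                      P_GXE = numeric(), P_MAIN = numeric(),
                      P_JOINT = numeric(), P_MARG = numeric(),
                      CLASS = character(), DRIVEN = logical(),
                      NOVEL = logical(), Z_SEXDIFF = numeric(),
                      P_SEXDIFF = numeric(), N_MEMBERS = integer(),
                      MEMBERS = character(), stringsAsFactors = FALSE)
  if (!eligibility(meta, config)) {
    message("meta-analysis not eligible for locus discovery ",
            "(N <= ", config$n_min, " and fewer than ",
            config$k_cohorts_min, " cohorts)")
    return(empty)
  }
  tab <- as.data.frame(exclude_mhc(meta))
  if (nrow(tab) == 0) return(empty)
  tab$Q_INT <- bh_fdr(tab$P_INT)
  tab$Q_JOINT <- bh_fdr(tab$P_JOINT)
  tab$Q_MARG <- bh_fdr(tab$P_MARG)

  ci <- select_1df(tab, config)
  cj <- select_2df(tab, config)
  ck <- two_step(tab, dosages, config)

  ids <- unique(c(ci$SNPID, cj$SNPID, ck$SNPID))
  if (length(ids) == 0) return(empty)
  sig <- tab[match(ids, tab$SNPID), , drop = FALSE]
  sig$ROUTE <- ifelse(sig$SNPID %in% ci$SNPID, "1df",
                      ifelse(sig$SNPID %in% ck$SNPID, "two-step", "2df"))
  sig$P <- ifelse(sig$ROUTE == "2df", sig$P_JOINT, sig$P_INT)
  sig$BETA <- sig$BETA_INT
  loci <- clump(sig, dosages, config)
  if (nrow(loci) == 0) return(empty)

  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lead <- sig[sig$SNPID == loci$LEAD_SNP[i], , drop = FALSE]
    cls <- classify_locus(lead, lead$ROUTE, known_bp_loci, known_gxe_loci,
                          config)
    out[[i]] <- data.frame(
      LOCUS_ID = sprintf("locus%03d", i), LEAD_SNP = lead$SNPID,
      CHR = lead$CHR, POS = lead$POS, ROUTE = lead$ROUTE,
      EXPOSURE = exposure, TRAIT = trait, SEX = sex_group,
      POP = population, P_GXE = lead$P_INT, P_MAIN = lead$P_MAIN,
      P_JOINT = lead$P_JOINT, P_MARG = lead$P_MARG, CLASS = cls$class,
      DRIVEN = cls$driven, NOVEL = cls$novel_bp,
      Z_SEXDIFF = NA_real_, P_SEXDIFF = NA_real_,
      N_MEMBERS = loci$N_MEMBERS[i], MEMBERS = loci$MEMBERS[i],
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  if (!is.null(female) && !is.null(male) && nrow(rep) > 0) {
    fi <- match(rep$LEAD_SNP, female$SNPID)
    mi <- match(rep$LEAD_SNP, male$SNPID)
    both <- !is.na(fi) & !is.na(mi)
    Q <- sum(both)
    if (Q > 0) {
      het <- sex_heterogeneity(female$BETA_INT[fi[both]],
                               female$SE_INT[fi[both]],
                               male$BETA_INT[mi[both]],
                               male$SE_INT[mi[both]], Q)
      rep$Z_SEXDIFF[both] <- het$Z
      rep$P_SEXDIFF[both] <- het$P
    }
  }
  rownames(rep) <- NULL
  rep
}
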