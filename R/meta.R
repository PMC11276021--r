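#' Align effect alleles across cohort summary tables
#'
#' The first table in which a variant appears defines its reference effect
#' allele. Tables reporting swapped alleles have their betas negated and the
#' effect-allele frequency complemented; irreconcilable allele pairs are
#' dropped with a message. Strand-ambiguous (A/T, C/G) variants are flagged
#' in a PALINDROMIC column but retained.
#'
#' @param tables named list of summary-statistics data.tables (cohort or
#'   group level).
#' @return list of aligned data.tables with a PALINDROMIC flag column.
#' @export
align_alleles <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- NULL
  beta_cols <- c("BETA_MARG", "BETA_MAIN", "BETA_INT",
                 "BETA_MAIN_2DF", "BETA_INT_2DF")
  out <- vector("list", length(tables))
  names(out) <- names(tables)
  for (i in seq_along(tables)) {
    tb <- data.table::copy(data.table::as.data.table(tables[[i]]))
    if (is.null(ref)) {
      ref <- tb[, c("SNPID", "EA", "OA")]
    } else {
      m <- match(tb$SNPID, ref$SNPID)
      new <- is.na(m)
      same <- !new & tb$EA == ref$EA[m] & tb$OA == ref$OA[m]
      flip <- !new & tb$EA == ref$OA[m] & tb$OA == ref$EA[m]
      bad <- !new & !same & !flip
      if (any(bad)) {
        message("dropping ", sum(bad), " variant(s) with irreconcilable ",
                "alleles in table ", i)
        tb <- tb[!bad]
        m <- m[!bad]; same <- same[!bad]; flip <- flip[!bad]; new <- new[!bad]
      }
      if (any(flip)) {
        for (bc in intersect(beta_cols, names(tb)))
          data.table::set(tb, which(flip), bc, -tb[[bc]][flip])
        data.table::set(tb, which(flip), "EAF", 1 - tb$EAF[flip])
        data.table::set(tb, which(flip), "EA", ref$EA[m][flip])
        data.table::set(tb, which(flip), "OA", ref$OA[m][flip])
      }
      if (any(new))
        ref <- rbind(ref, tb[new, c("SNPID", "EA", "OA")])
    }
    pal <- paste0(tb$EA, tb$OA) %in% c("AT", "TA", "CG", "GC")
    tb$PALINDROMIC <- pal
    out[[i]] <- tb
  }
  out
}

#' Inverse-variance-weighted fixed-effects meta-analysis (1 df)
#'
#' @param beta,se per-cohort estimates and standard errors (se > 0).
#' @return list with pooled \code{beta}, \code{se}, \code{z}, \code{p}.
#' @export
ivw_meta_1df <- function(beta, se) {
  if (length(beta) == 0) stop("no cohorts to meta-analyze")
  if (any(se <= 0)) stop("standard errors must be > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  wl <- wald_1df(b, s)
  list(beta = b, se = s, z = wl$z, p = wl$p)
}

#' Joint fixed-effects meta-analysis of (main, interaction) vectors (2 df)
#'
#' Pools per-cohort 2-vectors with their robust 2x2 covariances by
#' generalized least squares: V_meta = (sum V_i^-1)^-1,
#' beta_meta = V_meta sum V_i^-1 beta_i, chi^2 = beta' V_meta^-1 beta.
#'
#' @param betas list of length-2 vectors.
#' @param Vs list of 2x2 positive-definite covariance matrices.
#' @return list with \code{beta}, \code{V}, \code{chi2}, \code{p}.
#' @export
joint_meta_2df <- function(betas, Vs) {
  stopifnot(length(betas) == length(Vs), length(betas) >= 1)
  W <- matrix(0, 2, 2); Wb <- c(0, 0)
  for (i in seq_along(betas)) {
    Vi <- tryCatch(solve(Vs[[i]]), error = function(e) NULL)
    if (is.null(Vi)) { message("dropping cohort ", i, ": singular V"); next }
    W <- W + Vi
    Wb <- Wb + Vi %*% betas[[i]]
  }
  if (all(W == 0)) stop("no usable cohorts for joint meta")
  Vm <- solve(W)
  bm <- drop(Vm %*% Wb)
  chi2 <- drop(t(bm) %*% W %*% bm)
  log_p <- stats::pchisq(chi2, 2, lower.tail = FALSE, log.p = TRUE)
  list(beta = bm, V = Vm, chi2 = chi2, p = exp(log_p))
}

#' Genomic-control lambda
#'
#' Ratio of the observed median test statistic to the theoretical chi-square
#' median (0.4549364 for 1 df, 1.3862944 for 2 df). P-values are converted
#' to chi-square quantiles first when supplied instead of statistics.
#'
#' @param stat chi-square statistics (or p-values with \code{from_p = TRUE}).
#' @param df 1 or 2.
#' @param from_p treat \code{stat} as p-values.
#' @param min_n minimum number of statistics required (default 100); below
#'   it lambda is returned as 1 with a warning.
#' @return scalar lambda.
#' @export
genomic_lambda <- function(stat, df = 1, from_p = FALSE, min_n = 100) {
  stat <- stat[is.finite(stat)]
  if (length(stat) < min_n) {
    warning("fewer than ", min_n, " statistics; lambda fixed at 1")
    return(1)
  }
  if (from_p) stat <- stats::qchisq(stat, df = df, lower.tail = FALSE)
  stats::median(stat) / stats::qchisq(0.5, df = df)
}

#' Apply genomic-control correction to a meta (or cohort) table
#'
#' For each 1 df effect family the SE is inflated by sqrt(max(lambda, 1))
#' and the p-value recomputed; the 2 df statistic is divided by
#' max(lambda_joint, 1) (equivalently its pooled covariance is inflated) and
#' its p recomputed. Lambda below 1 never deflates.
#'
#' @param tab summary table with BETA_/SE_/P_ columns.
#' @param lambdas named list or vector with elements \code{marg},
#'   \code{main}, \code{int}, \code{joint}.
#' @return corrected copy of \code{tab}.
#' @export
gc_correct <- function(tab, lambdas) {
  tab <- data.table::copy(data.table::as.data.table(tab))
  lam <- function(x) {
    l <- lambdas[[x]]
    if (is.null(l) || !is.finite(l)) l <- 1
    max(l, 1)
  }
  fams <- list(marg = c("BETA_MARG", "SE_MARG", "P_MARG"),
               main = c("BETA_MAIN", "SE_MAIN", "P_MAIN"),
               int = c("BETA_INT", "SE_INT", "P_INT"))
  for (f in names(fams)) {
    cols <- fams[[f]]
    if (!all(cols %in% names(tab))) next
    l <- lam(f)
    if (l > 1) {
      data.table::set(tab, j = cols[2], value = tab[[cols[2]]] * sqrt(l))
      data.table::set(tab, j = cols[3],
                      value = wald_1df(tab[[cols[1]]], tab[[cols[2]]])$p)
    }
  }
  if ("CHISQ_JOINT" %in% names(tab)) {
    l2 <- lam("joint")
    if (l2 > 1) {
      data.table::set(tab, j = "CHISQ_JOINT", value = tab$CHISQ_JOINT / l2)
      for (vc in intersect(c("SE_MAIN_2DF", "SE_INT_2DF"), names(tab)))
        data.table::set(tab, j = vc, value = tab[[vc]] * sqrt(l2))
      if ("COV_MAIN_INT" %in% names(tab))
        data.table::set(tab, j = "COV_MAIN_INT",
                        value = tab$COV_MAIN_INT * l2)
      data.table::set(tab, j = "P_JOINT",
                      value = exp(stats::pchisq(tab$CHISQ_JOINT, 2,
                                                lower.tail = FALSE,
                                                log.p = TRUE)))
    }
  }
  tab
}

# Fixed-effects pooling engine shared by the population-group and
# cross-population levels. Inputs must be allele-aligned. The 2 df vector is
# taken from the *_2DF columns when present (group-level input), otherwise
# from the M1 BETA_MAIN/BETA_INT columns (cohort-level input).
.meta_engine <- function(tables) {
  pieces <- vector("list", length(tables))
  cnames <- if (is.null(names(tables))) paste0("c", seq_along(tables))
            else names(tables)
  for (i in seq_along(tables)) {
    tb <- data.table::as.data.table(tables[[i]])
    if (nrow(tb) == 0) next
    b1 <- if ("BETA_MAIN_2DF" %in% names(tb)) tb$BETA_MAIN_2DF else tb$BETA_MAIN
    b2 <- if ("BETA_INT_2DF" %in% names(tb)) tb$BETA_INT_2DF else tb$BETA_INT
    s1 <- if ("SE_MAIN_2DF" %in% names(tb)) tb$SE_MAIN_2DF else tb$SE_MAIN
    s2 <- if ("SE_INT_2DF" %in% names(tb)) tb$SE_INT_2DF else tb$SE_INT
    pieces[[i]] <- data.table::data.table(
      SNPID = tb$SNPID, CHR = tb$CHR, POS = tb$POS, EA = tb$EA, OA = tb$OA,
      EAF = tb$EAF, N = tb$N,
      K = if ("K_COHORTS" %in% names(tb)) tb$K_COHORTS else 1L,
      BMARG = tb$BETA_MARG, SEMARG = tb$SE_MARG,
      BMAIN = tb$BETA_MAIN, SEMAIN = tb$SE_MAIN,
      BINT = tb$BETA_INT, SEINT = tb$SE_INT,
      B1 = b1, B2 = b2, V11 = s1^2, V12 = tb$COV_MAIN_INT, V22 = s2^2,
      COHORT = cnames[i])
  }
  dt <- data.table::rbindlist(pieces)
  if (nrow(dt) == 0) stop("no rows to meta-analyze")
  # 2x2 inverse elements per row
  dt[, `:=`(det = V11 * V22 - V12^2)]
  dt[, `:=`(ia = V22 / det, ib = -V12 / det, id = V11 / det)]
  dt[, `:=`(iu = ia * B1 + ib * B2, iv = ib * B1 + id * B2)]
  agg <- dt[, {
    wmar <- 1 / SEMARG^2; wmai <- 1 / SEMAIN^2; wint <- 1 / SEINT^2
    A <- sum(ia); Bc <- sum(ib); D <- sum(id)
    U <- sum(iu); Vv <- sum(iv)
    detW <- A * D - Bc^2
    vm11 <- D / detW; vm12 <- -Bc / detW; vm22 <- A / detW
    bm1 <- vm11 * U + vm12 * Vv
    bm2 <- vm12 * U + vm22 * Vv
    chi2 <- U * bm1 + Vv * bm2
    o <- order(COHORT)
    list(CHR = CHR[1], POS = POS[1], EA = EA[1], OA = OA[1],
         EAF = sum(EAF * N) / sum(N), N = sum(N),
         K_COHORTS = sum(K),
         BETA_MARG = sum(wmar * BMARG) / sum(wmar),
         SE_MARG = sqrt(1 / sum(wmar)),
         BETA_MAIN = sum(wmai * BMAIN) / sum(wmai),
         SE_MAIN = sqrt(1 / sum(wmai)),
         BETA_INT = sum(wint * BINT) / sum(wint),
         SE_INT = sqrt(1 / sum(wint)),
         BETA_MAIN_2DF = bm1, BETA_INT_2DF = bm2,
         SE_MAIN_2DF = sqrt(vm11), SE_INT_2DF = sqrt(vm22),
         COV_MAIN_INT = vm12, CHISQ_JOINT = chi2,
         DIRECTIONS = paste(ifelse(BINT[o] > 0, "+",
                                   ifelse(BINT[o] < 0, "-", "0")),
                            collapse = ""))
  }, by = "SNPID"]
  for (f in list(c("BETA_MARG", "SE_MARG", "P_MARG"),
                 c("BETA_MAIN", "SE_MAIN", "P_MAIN"),
                 c("BETA_INT", "SE_INT", "P_INT")))
    agg[[f[3]]] <- wald_1df(agg[[f[1]]], agg[[f[2]]])$p
  agg$P_JOINT <- exp(stats::pchisq(agg$CHISQ_JOINT, 2, lower.tail = FALSE,
                                   log.p = TRUE))
  data.table::setorder(agg, CHR, POS, EA, OA)
  agg
}

.table_lambdas <- function(tab, min_n = 100) {
  suppressWarnings(list(
    marg = genomic_lambda((tab$BETA_MARG / tab$SE_MARG)^2, 1, min_n = min_n),
    main = genomic_lambda((tab$BETA_MAIN / tab$SE_MAIN)^2, 1, min_n = min_n),
    int = genomic_lambda((tab$BETA_INT / tab$SE_INT)^2, 1, min_n = min_n),
    joint = genomic_lambda(tab$CHISQ_JOINT, 2, min_n = min_n)))
}

#' Population-group meta-analysis of cohort summary statistics
#'
#' Aligns alleles, pools each 1 df effect family by inverse-variance
#' weighting and the (main, interaction) vector by the joint 2 df method,
#' then applies genomic-control correction with lambdas computed from the
#' pooled statistics (one lambda per effect family). Variants present in at
#' least one cohort are meta-analyzed; eligibility thresholds are applied
#' downstream at locus discovery.
#'
#' @param tables named list of cohort summary-statistics tables (one
#'   analysis, i.e. one trait x exposure x sex-group combination).
#' @param gc apply genomic-control correction (default TRUE).
#' @param lambda_min_n minimum variants for estimating lambda.
#' @return pooled data.table with a \code{lambda_report} attribute.
#' @export
population_meta <- function(tables, gc = TRUE, lambda_min_n = 100) {
  tables <- tables[vapply(tables, nrow, integer(1)) > 0]
  if (length(tables) == 0) stop("no non-empty cohort tables")
  aligned <- align_alleles(tables)
  agg <- .meta_engine(aligned)
  lambdas <- .table_lambdas(agg, min_n = lambda_min_n)
  if (gc) agg <- gc_correct(agg, lambdas)
  attr(agg, "lambda_report") <- lambdas
  agg
}

#' Cross-population meta-analysis of population-group results
#'
#' Second-level fixed-effects meta treating each population-group estimate
#' as one input, followed by a second genomic-control pass on the pooled
#' statistics. Group-level 2 df vectors and covariances (already
#' GC-corrected at the group level) are carried through unchanged.
#'
#' @param group_tables named list of \code{\link{population_meta}} outputs.
#' @inheritParams population_meta
#' @return pooled data.table with a \code{lambda_report} attribute.
#' @export
cross_population_meta <- function(group_tables, gc = TRUE,
                                  lambda_min_n = 100) {
  group_tables <- group_tables[vapply(group_tables, nrow, integer(1)) > 0]
  if (length(group_tables) == 0) stop("no non-empty group tables")
  aligned <- align_alleles(group_tables)
  agg <- .meta_engine(aligned)
  lambdas <- .table_lambdas(agg, min_n = lambda_min_n)
  if (gc) agg <- gc_correct(agg, lambdas)
  attr(agg, "lambda_report") <- lambdas
  agg
}

#' Flag allele-frequency discrepancies against a reference
#'
#' @param tab summary table with SNPID and EAF.
#' @param ref data.frame with SNPID and AF_REF (here: the simulation's true
#'   population frequencies).
#' @param tol absolute frequency tolerance (default 0.2).
#' @return copy of \code{tab} with logical AF_FLAG (NA when no reference).
#' @export
qc_allele_freq <- function(tab, ref, tol = 0.2) {
  tab <- data.table::copy(data.table::as.data.table(tab))
  m <- match(tab$SNPID, ref$SNPID)
  flag <- abs(tab$EAF - ref$AF_REF[m]) > tol
  if (any(is.na(m)))
    message(sum(is.na(m)), " variant(s) without reference AF left unflagged")
  tab$AF_FLAG <- flag
  tab
}
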