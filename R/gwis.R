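#' Ordinary least squares fit
#'
#' @param X full-column-rank design matrix.
#' @param y response vector of matching length.
#' @return list with \code{coef}, \code{residuals} and \code{XtX_inv}.
#' @export
ols_fit <- function(X, y) {
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  XtX_inv <- chol2inv(R)
  coef <- drop(XtX_inv %*% crossprod(X, y))
  names(coef) <- colnames(X)
  list(coef = coef, residuals = drop(y - X %*% coef), XtX_inv = XtX_inv)
}

#' Heteroskedasticity-robust (sandwich) covariance of OLS coefficients
#'
#' HC0: (X'X)^-1 X' diag(r^2) X (X'X)^-1. HC1 applies the n/(n-k)
#' small-sample factor; HC3 scales residuals by 1/(1 - h_i).
#'
#' @param X design matrix of the fitted model.
#' @param residuals fitted residuals.
#' @param type "HC0" (default), "HC1" or "HC3".
#' @param XtX_inv optional precomputed inverse cross-product.
#' @return robust covariance matrix of the coefficient vector.
#' @export
robust_covariance <- function(X, residuals, type = c("HC0", "HC1", "HC3"),
                              XtX_inv = NULL) {
  type <- match.arg(type)
  n <- nrow(X); k <- ncol(X)
  if (is.null(XtX_inv)) {
    R <- tryCatch(chol(crossprod(X)), error = function(e)
      stop("X'X is singular"))
    XtX_inv <- chol2inv(R)
  }
  r <- residuals
  if (type == "HC3") {
    h <- rowSums((X %*% XtX_inv) * X)
    r <- r / (1 - h)
  }
  meat <- crossprod(X * r)
  V <- XtX_inv %*% meat %*% XtX_inv
  if (type == "HC1") V <- V * n / (n - k)
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' One-degree-of-freedom Wald test
#'
#' z = beta/se with a two-sided normal p computed in log space, so p-values
#' far below double underflow (z > 38) remain representable through
#' \code{log_p}.
#'
#' @param beta,se estimate and (robust) standard error; vectorized.
#' @return list with \code{z}, \code{p} and natural-log \code{log_p}.
#' @export
wald_1df <- function(beta, se) {
  if (any(se <= 0)) stop("standard errors must be > 0")
  z <- beta / se
  log_p <- log(2) + stats::pnorm(-abs(z), log.p = TRUE)
  list(z = z, p = exp(log_p), log_p = log_p)
}

#' Two-degree-of-freedom joint Wald test of main and interaction effects
#'
#' chi^2 = beta' V^-1 beta with a chi-square 2 df upper-tail p in log space.
#'
#' @param beta length-2 vector (beta_G, beta_GxE).
#' @param V 2x2 symmetric positive-definite robust covariance.
#' @return list with \code{chi2}, \code{p}, \code{log_p}.
#' @export
wald_2df <- function(beta, V) {
  R <- tryCatch(chol(V), error = function(e)
    stop("joint-test covariance is not positive definite"))
  chi2 <- drop(crossprod(backsolve(R, beta, transpose = TRUE)))
  log_p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE, log.p = TRUE)
  list(chi2 = chi2, p = exp(log_p), log_p = log_p)
}

#' Variant-level filter configuration
#'
#' @param maf_min minimum minor allele frequency (default 0.001).
#' @param rsq_min minimum imputation quality (default 0.3).
#' @param df_min minimum MAC x R^2 in each of the exposed, unexposed and
#'   total samples (default 20).
#' @return a \code{filter_config}.
#' @export
filter_config <- function(maf_min = 0.001, rsq_min = 0.3, df_min = 20) {
  stopifnot(maf_min > 0, rsq_min > 0, df_min > 0)
  structure(list(maf_min = maf_min, rsq_min = rsq_min, df_min = df_min),
            class = "filter_config")
}

#' Apply variant-level QC filters
#'
#' Drops variants with MAF < maf_min, imputation R^2 < rsq_min, or
#' MAC x R^2 < df_min in any of the exposed, unexposed or total samples;
#' drops duplicated chrom:pos:allele records, monomorphic variants, and
#' non-autosomal records. MAC is min(sum g, 2n - sum g) within the subgroup,
#' computed on dosages.
#'
#' @param variants variant table (id, chrom, pos, ea, oa, rsq).
#' @param dosages variants x samples dosage matrix.
#' @param exposure 0/1 exposure vector over samples.
#' @param config a \code{\link{filter_config}}.
#' @return data.frame: id, keep, reason, maf, df_tot, df_exp, df_unexp.
#' @export
variant_filters <- function(variants, dosages, exposure,
                            config = filter_config()) {
  n <- ncol(dosages)
  exp_idx <- exposure == 1
  mac_of <- function(M) {
    cs <- rowSums(M)
    pmin(cs, 2 * ncol(M) - cs)
  }
  mac_tot <- mac_of(dosages)
  mac_exp <- mac_of(dosages[, exp_idx, drop = FALSE])
  mac_une <- mac_of(dosages[, !exp_idx, drop = FALSE])
  af <- rowSums(dosages) / (2 * n)
  maf <- pmin(af, 1 - af)
  df_tot <- mac_tot * variants$rsq
  df_exp <- mac_exp * variants$rsq
  df_une <- mac_une * variants$rsq
  mono <- apply(dosages, 1, function(g) stats::var(g) == 0)
  key <- paste(variants$chrom, variants$pos,
               pmin(variants$ea, variants$oa),
               pmax(variants$ea, variants$oa), sep = ":")
  dup <- duplicated(key)
  autosome <- variants$chrom %in% 1:22

  reason <- rep(NA_character_, nrow(variants))
  reason[df_tot < config$df_min | df_exp < config$df_min |
           df_une < config$df_min] <- "df"
  reason[variants$rsq < config$rsq_min] <- "rsq"
  reason[maf < config$maf_min] <- "maf"
  reason[mono] <- "monomorphic"
  reason[dup] <- "duplicate"
  reason[!autosome] <- "non-autosomal"
  data.frame(id = variants$id, keep = is.na(reason), reason = reason,
             maf = maf, af = af, df_tot = df_tot, df_exp = df_exp,
             df_unexp = df_une, stringsAsFactors = FALSE)
}

#' Fit the interaction (M1) and marginal (M2) models for one variant
#'
#' M1 regresses the trait on \[C1 | G | E.G\] and M2 on \[C2 | G\], both with
#' the requested heteroskedasticity-robust covariance. The (beta_G,
#' beta_GxE) block of the M1 robust covariance, including its off-diagonal
#' term, feeds the 2 df joint test.
#'
#' @param g dosage vector.
#' @param y trait vector.
#' @param E 0/1 exposure vector.
#' @param C1,C2 design matrices from \code{\link{build_designs}}.
#' @param robust robust covariance flavour.
#' @return one-row list of estimates and p-values, or NULL when the variant
#'   is degenerate in this stratum (constant dosage or no exposed carriers).
#' @export
fit_variant <- function(g, y, E, C1, C2, robust = "HC0") {
  ge <- g * E
  if (stats::var(g) == 0 || all(ge == 0)) return(NULL)
  X1 <- cbind(C1, G = g, GxE = ge)
  f1 <- tryCatch(ols_fit(X1, y), error = function(e) NULL)
  if (is.null(f1)) return(NULL)
  V1 <- robust_covariance(X1, f1$residuals, robust, XtX_inv = f1$XtX_inv)
  k <- ncol(X1)
  idx <- c(k - 1L, k)
  b2 <- f1$coef[idx]
  Vb <- V1[idx, idx]

  X2 <- cbind(C2, G = g)
  f2 <- ols_fit(X2, y)
  V2 <- robust_covariance(X2, f2$residuals, robust, XtX_inv = f2$XtX_inv)
  bm <- f2$coef[ncol(X2)]
  sem <- sqrt(V2[ncol(X2), ncol(X2)])

  w_main <- wald_1df(b2[1], sqrt(Vb[1, 1]))
  w_int <- wald_1df(b2[2], sqrt(Vb[2, 2]))
  w_marg <- wald_1df(bm, sem)
  w_joint <- wald_2df(b2, Vb)
  list(beta_marg = unname(bm), se_marg = sem,
       beta_main = unname(b2[1]), se_main = sqrt(Vb[1, 1]),
       beta_int = unname(b2[2]), se_int = sqrt(Vb[2, 2]),
       cov_main_int = Vb[1, 2],
       p_marg = w_marg$p, p_main = w_main$p, p_int = w_int$p,
       p_joint = w_joint$p, chi2_joint = w_joint$chi2)
}

#' Genome-wide gene-by-sleep interaction scan for one cohort
#'
#' Runs the per-variant M1/M2 fits for every requested trait x exposure x
#' sex-group combination (all 18 by default), applying the variant filters
#' within each combination's stratum. Rows are ordered by chromosome and
#' position; output columns follow the summary-statistics exchange format.
#'
#' @param hc a \code{harmonized_cohort}.
#' @param traits,exposures,sex_groups combinations to run.
#' @param filter a \code{\link{filter_config}}.
#' @param robust robust covariance flavour ("HC0", "HC1", "HC3").
#' @return named list of data.tables, one per combination
#'   ("SBP.STST.combined", ...).
#' @export
gwis_scan <- function(hc, traits = c("SBP", "DBP", "PP"),
                      exposures = c("STST", "LTST"),
                      sex_groups = c("combined", "female", "male"),
                      filter = filter_config(), robust = "HC0") {
  stopifnot(inherits(hc, "harmonized_cohort"))
  ph <- hc$pheno
  ord <- order(hc$variants$chrom, hc$variants$pos, hc$variants$ea,
               hc$variants$oa)
  variants <- hc$variants[ord, , drop = FALSE]
  dosages <- hc$dosages[ord, , drop = FALSE]
  out <- list()
  for (sx in sex_groups) {
    rows <- switch(sx, combined = rep(TRUE, nrow(ph)),
                   female = ph$sex == 1, male = ph$sex == 0)
    phs <- ph[rows, , drop = FALSE]
    ds <- dosages[, rows, drop = FALSE]
    for (ex in exposures) {
      E <- if (ex == "STST") phs$stst else phs$ltst
      empty <- .empty_sumstats()
      if (sum(E) < 2) {
        warning("fewer than 2 exposed samples for ", ex, " in ", sx,
                " stratum; emitting empty tables")
        for (tr in traits) out[[paste(tr, ex, sx, sep = ".")]] <- empty
        next
      }
      flt <- variant_filters(variants, ds, E, filter)
      designs <- build_designs(phs, E, sex_group = sx)
      keep <- which(flt$keep)
      for (tr in traits) {
        y <- phs[[tolower(tr)]]
        recs <- vector("list", length(keep))
        for (i in seq_along(keep)) {
          v <- keep[i]
          r <- fit_variant(ds[v, ], y, E, designs$C1, designs$C2, robust)
          if (is.null(r)) next
          recs[[i]] <- list(
            SNPID = variants$id[v], CHR = variants$chrom[v],
            POS = variants$pos[v], EA = variants$ea[v], OA = variants$oa[v],
            EAF = flt$af[v], N = nrow(phs),
            BETA_MARG = r$beta_marg, SE_MARG = r$se_marg,
            BETA_MAIN = r$beta_main, SE_MAIN = r$se_main,
            BETA_INT = r$beta_int, SE_INT = r$se_int,
            COV_MAIN_INT = r$cov_main_int,
            P_MARG = r$p_marg, P_MAIN = r$p_main, P_INT = r$p_int,
            P_JOINT = r$p_joint,
            DF_TOT = flt$df_tot[v], DF_EXP = flt$df_exp[v],
            DF_UNEXP = flt$df_unexp[v])
        }
        tab <- data.table::rbindlist(recs[!vapply(recs, is.null, logical(1))])
        if (nrow(tab) == 0) tab <- empty
        out[[paste(tr, ex, sx, sep = ".")]] <- tab
      }
    }
  }
  out
}

.empty_sumstats <- function() {
  data.table::data.table(
    SNPID = character(), CHR = integer(), POS = integer(),
    EA = character(), OA = character(), EAF = numeric(), N = integer(),
    BETA_MARG = numeric(), SE_MARG = numeric(), BETA_MAIN = numeric(),
    SE_MAIN = numeric(), BETA_INT = numeric(), SE_INT = numeric(),
    COV_MAIN_INT = numeric(), P_MARG = numeric(), P_MAIN = numeric(),
    P_INT = numeric(), P_JOINT = numeric(), DF_TOT = numeric(),
    DF_EXP = numeric(), DF_UNEXP = numeric())
}
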