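test_that("eligibility needs N strictly above 20000 or at least 3 cohorts", {
  base <- make_meta_table(3, seed = 41)
  t1 <- data.table::copy(base); t1$N <- 20001L; t1$K_COHORTS <- 1L
  t2 <- data.table::copy(base); t2$N <- 20000L; t2$K_COHORTS <- 3L
  t3 <- data.table::copy(base); t3$N <- 20000L; t3$K_COHORTS <- 2L
  expect_true(eligibility(t1))
  expect_true(eligibility(t2))
  expect_false(eligibility(t3))
})

test_that("MHC masking drops chr6 hits inside the buffered interval only", {
  tab <- data.frame(CHR = c(6, 6, 7, 6, 6),
                    POS = c(30000000, 27510119, 30000000, 27510120, 34480578))
  kept <- exclude_mhc(tab)
  expect_equal(nrow(kept), 3)
  expect_false(any(kept$CHR == 6 & kept$POS == 30000000))  # inside MHC
  expect_false(any(kept$POS == 27510120))                  # buffer start
  expect_true(any(kept$POS == 27510119))                   # 1 bp outside
  expect_true(any(kept$CHR == 7))                          # wrong chromosome
  expect_true(any(kept$POS == 34480578))                   # 1 bp past buffer end
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(42)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(q, p.adjust(p, "BH"))
})

test_that("1 df and 2 df selections apply both the p and FDR criteria independently", {
  tab <- make_meta_table(4, seed = 43)
  tab$P_INT <- c(4e-9, 6e-9, 0.5, 0.9)
  tab$Q_INT <- bh_fdr(tab$P_INT)
  tab$P_JOINT <- c(0.5, 1e-10, 1e-8, 0.9)
  tab$Q_JOINT <- bh_fdr(tab$P_JOINT)
  expect_identical(select_1df(tab)$SNPID, tab$SNPID[1])
  expect_identical(select_2df(tab)$SNPID, tab$SNPID[2])  # routes independent
})

test_that("effective number of tests tracks the LD block structure", {
  set.seed(44)
  n <- 400
  # orthogonalized independent variants: exact zero correlation
  raw <- matrix(rnorm(6 * n), n, 6)
  orth <- qr.Q(qr(raw))
  ds_ind <- t(orth) + 1
  expect_equal(effective_tests(ds_ind), 6L)
  # one variant duplicated: rank 1
  g <- rbinom(n, 2, 0.3)
  expect_equal(effective_tests(rbind(g, g, g, g, g)), 1L)
  # two perfect blocks of five
  g2 <- rbinom(n, 2, 0.4)
  blocks <- rbind(g, g, g, g, g, g2, g2, g2, g2, g2)
  expect_equal(effective_tests(blocks), 2L)
  # N_G never increases when LD is added
  noise <- matrix(rbinom(10 * n, 2, 0.3), 10, n)
  expect_gte(effective_tests(noise), effective_tests(blocks))
})

test_that("two-step screening applies the PCA-adjusted Bonferroni threshold", {
  tab <- make_meta_table(12, seed = 45)
  tab$P_MARG <- c(1e-6, rep(0.5, 11))
  tab$P_INT <- c(0.04, runif(11, 0.2, 1))
  k1 <- two_step(tab)
  expect_identical(k1$SNPID, tab$SNPID[1])    # z = 1, threshold 0.05
  expect_equal(attr(k1, "N_G"), 1L)
  # ten independent screened variants: threshold 0.005 rejects p = 0.04
  tab$P_MARG <- c(rep(1e-6, 10), 0.5, 0.5)
  tab$P_INT <- c(0.04, runif(9, 0.5, 1), 0.5, 0.5)
  set.seed(46)
  ds <- matrix(rbinom(10 * 2000, 2, 0.3), 10, 2000,
               dimnames = list(tab$SNPID[1:10], NULL))
  k10 <- two_step(tab, ds)
  expect_equal(nrow(k10), 0)
  expect_gte(attr(k10, "N_G"), 9L)
  # no screened variants: empty class
  tab$P_MARG <- rep(0.5, 12)
  expect_equal(nrow(two_step(tab)), 0)
})

test_that("LD r2 is symmetric in allele coding and near zero for independent variants", {
  set.seed(47)
  g1 <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  r2 <- replicate(100, ld_r2(g1, rbinom(5000, 2, 0.3)))
  expect_gte(mean(r2 < 0.01), 0.95)
  expect_warning(z <- ld_r2(g1, rep(1, 5000)), "constant")
  expect_equal(z, 0)
})

test_that("clumping groups by 500 kb radius, merges LD-dependent leads, ignores row order", {
  set.seed(48)
  ds <- matrix(rbinom(4 * 3000, 2, 0.3), 4, 3000,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  sig1 <- data.frame(SNPID = "a", CHR = 1, POS = 1e6, P = 1e-10, BETA = -2)
  one <- clump(sig1, ds)
  expect_equal(nrow(one), 1)
  expect_equal(one$LEAD_SNP, "a")
  near <- data.frame(SNPID = c("a", "b"), CHR = 1, POS = c(1e6, 1.4e6),
                     P = c(1e-10, 1e-9), BETA = c(-2, -1.5))
  expect_equal(nrow(clump(near, ds)), 1)          # 400 kb apart: one locus
  far <- data.frame(SNPID = c("a", "b"), CHR = 1, POS = c(1e6, 1.6e6),
                    P = c(1e-10, 1e-9), BETA = c(-2, -1.5))
  expect_equal(nrow(clump(far, ds)), 2)           # 600 kb + r2 < 0.1: two loci
  # dependent leads collapse into the stronger locus
  ds2 <- ds; ds2["b", ] <- ds2["a", ]
  expect_equal(nrow(clump(far, ds2)), 1)
  expect_equal(clump(far, ds2)$LEAD_SNP, "a")
  # row order does not matter
  sh <- far[2:1, ]
  expect_equal(clump(sh, ds), clump(far, ds))
  # members partition the significant set
  multi <- data.frame(SNPID = c("a", "b", "c", "d"), CHR = c(1, 1, 1, 2),
                      POS = c(1e6, 1.3e6, 2.6e6, 1e6),
                      P = c(1e-10, 1e-9, 1e-8, 1e-7),
                      BETA = c(-2, 1, 1, 1))
  cl <- clump(multi, ds)
  members <- sort(unlist(strsplit(cl$MEMBERS, ",")))
  expect_identical(members, sort(multi$SNPID))
  expect_equal(sum(cl$N_MEMBERS), 4)
})

test_that("locus classification follows the driven/supported and novelty rules", {
  lead <- data.frame(CHR = 2, POS = 50e6, P_INT = 1e-10, P_MAIN = 1e-3,
                     P_MARG = 0.2, Q_MARG = 0.6)
  far_known <- data.frame(chrom = 2, pos = 10e6)
  y <- classify_locus(lead, "2df", known_bp = far_known)
  expect_equal(y$class, "Y")
  expect_true(y$driven)
  supp <- lead; supp$P_INT <- 1e-4; supp$P_MAIN <- 1e-7
  z <- classify_locus(supp, "2df", known_bp = far_known)
  expect_equal(z$class, "Z")
  expect_false(z$driven)
  # 0.9 Mb from a known BP locus: excluded from the novel classes
  near_known <- data.frame(chrom = 2, pos = 50e6 - 0.9e6)
  excl <- classify_locus(lead, "2df", known_bp = near_known)
  expect_true(is.na(excl$class))
  expect_false(excl$novel_bp)
  # significant marginal effect blocks 2 df prioritization
  margsig <- lead; margsig$P_MARG <- 1e-10; margsig$Q_MARG <- 1e-8
  expect_true(is.na(classify_locus(margsig, "2df",
                                   known_bp = far_known)$class))
  # 1 df route: novelty vs known interaction loci
  x <- classify_locus(lead, "1df", known_bp = far_known,
                      known_gxe = far_known)
  expect_equal(x$class, "X")
  xnear <- classify_locus(lead, "1df", known_bp = far_known,
                          known_gxe = near_known)
  expect_true(is.na(xnear$class))
  # no known-loci table: novelty unknown, not claimed novel
  unk <- classify_locus(lead, "1df")
  expect_true(is.na(unk$novel_bp))
})

test_that("sex-heterogeneity Z-test matches the normal-tail oracle and Bonferroni rule", {
  h <- sex_heterogeneity(1, 0.5, -1, 0.5, Q = 1)
  expect_equal(h$Z, 2.828427, tolerance = 1e-6)
  expect_equal(h$P, 2 * pnorm(-2 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(h$P, 0.004677735, tolerance = 1e-6)
  same <- sex_heterogeneity(0.7, 0.3, 0.7, 0.4, Q = 5)
  expect_equal(same$Z, 0)
  expect_equal(same$P, 1)
  # threshold arithmetic at Q = 22
  q22 <- sex_heterogeneity(2, 0.457, 0, 0.457, Q = 22)
  expect_equal(round(q22$P, 3), 0.002)
  expect_true(q22$P < 0.05 / 22)
  expect_true(q22$SIGNIFICANT)
})

test_that("discover_loci ties routes, clumping and classification together", {
  set.seed(49)
  tab <- make_meta_table(60, seed = 49, n_samples = 30000L)
  tab$CHR <- rep(1:6, each = 10)
  tab$POS <- rep(seq(10e6, 100e6, by = 10e6), 6)
  # one clean 1 df interaction hit
  tab$P_INT[5] <- 1e-12
  tab$BETA_INT[5] <- -5
  # one 2 df-only hit with insignificant marginal effect
  tab$P_JOINT[20] <- 1e-11
  tab$P_INT[20] <- 1e-4
  tab$P_MARG[20] <- 0.3
  ds <- matrix(rbinom(60 * 2000, 2, 0.3), 60, 2000,
               dimnames = list(tab$SNPID, NULL))
  rep <- discover_loci(tab, dosages = ds, trait = "SBP", exposure = "STST",
                       sex_group = "combined", population = "CPMA")
  expect_equal(nrow(rep), 2)
  r5 <- rep[rep$LEAD_SNP == tab$SNPID[5], ]
  expect_equal(r5$ROUTE, "1df")
  expect_equal(r5$CLASS, "X")
  r20 <- rep[rep$LEAD_SNP == tab$SNPID[20], ]
  expect_equal(r20$ROUTE, "2df")
  expect_true(r20$CLASS %in% c("Y", "Z"))
  # ineligible meta yields no loci
  small <- data.table::copy(tab)
  small$N <- 5000L; small$K_COHORTS <- 1L
  expect_message(none <- discover_loci(small, dosages = ds), "not eligible")
  expect_equal(nrow(none), 0)
  # sex heterogeneity is attached when both strata carry the lead
  fem <- data.table::copy(tab); fem$BETA_INT[5] <- -7; fem$SE_INT[5] <- 0.8
  mal <- data.table::copy(tab); mal$BETA_INT[5] <- -1; mal$SE_INT[5] <- 0.8
  rep2 <- discover_loci(tab, dosages = ds, female = fem, male = mal)
  z <- rep2$Z_SEXDIFF[rep2$LEAD_SNP == tab$SNPID[5]]
  expect_equal(z, (-7 - -1) / sqrt(2 * 0.8^2), tolerance = 1e-10)
})
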