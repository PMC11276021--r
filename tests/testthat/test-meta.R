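test_that("allele alignment flips swapped records and flags palindromes", {
  a <- make_sumstats(4, seed = 31)
  a$EA <- c("A", "A", "C", "A"); a$OA <- c("G", "T", "G", "C")
  b <- data.table::copy(a)
  # cohort B reports variant 1 on the opposite allele
  b$EA[1] <- "G"; b$OA[1] <- "A"
  b$BETA_INT[1] <- 2; b$EAF[1] <- 0.3
  al <- align_alleles(list(A = a, B = b))
  expect_equal(al$B$BETA_INT[1], -2)
  expect_equal(al$B$EAF[1], 0.7)
  expect_equal(al$B$EA[1], "A")
  expect_identical(al$B$BETA_MARG[2:4], b$BETA_MARG[2:4])  # identical rows pass through
  expect_identical(al$A$PALINDROMIC, c(FALSE, TRUE, TRUE, FALSE))
  # irreconcilable alleles are dropped
  cbad <- data.table::copy(a)
  cbad$EA[2] <- "C"; cbad$OA[2] <- "G"
  expect_message(al2 <- align_alleles(list(A = a, C = cbad)), "irreconcilable")
  expect_false("var00002" %in% al2$C$SNPID)
})

test_that("inverse-variance meta matches hand-computed pooling", {
  one <- ivw_meta_1df(1.7, 0.42)
  expect_equal(one$beta, 1.7)
  expect_equal(one$se, 0.42)
  eq <- ivw_meta_1df(c(1, 3), c(0.5, 0.5))
  expect_equal(eq$beta, 2)
  expect_equal(eq$se, 0.5 / sqrt(2))
  hand <- ivw_meta_1df(c(1.0, 2.0), c(0.5, 1.0))
  expect_equal(hand$beta, 1.2)
  expect_equal(hand$se, 0.4472136, tolerance = 1e-6)
  expect_equal(hand$se^2, 1 / sum(c(0.5, 1)^-2), tolerance = 1e-12)
  expect_error(ivw_meta_1df(numeric(0), numeric(0)), "no cohorts")
})

test_that("joint 2 df meta matches the stacked GLS oracle and closed forms", {
  set.seed(32)
  b <- c(0.8, -1.4)
  A <- matrix(rnorm(4), 2); V <- crossprod(A) + diag(2) * 0.2
  single <- joint_meta_2df(list(b), list(V))
  expect_equal(single$beta, b)
  expect_equal(single$chi2, wald_2df(b, V)$chi2, tolerance = 1e-12)
  K <- 4
  rep4 <- joint_meta_2df(rep(list(b), K), rep(list(V), K))
  expect_equal(rep4$V, V / K, tolerance = 1e-12)
  expect_equal(rep4$beta, b)
  # brute-force GLS on the stacked system with distinct covariances
  betas <- list(c(1, 0.5), c(0.4, -0.2), c(0.7, 0.1))
  Vs <- lapply(1:3, function(i) {
    A <- matrix(rnorm(4), 2); crossprod(A) + diag(2) * 0.3
  })
  X <- do.call(rbind, rep(list(diag(2)), 3))
  y <- unlist(betas)
  Sigma <- matrix(0, 6, 6)
  for (i in 1:3) Sigma[2 * i - 1:0, 2 * i - 1:0] <- Vs[[i]]
  Sigma_inv <- solve(Sigma)
  gls_V <- solve(t(X) %*% Sigma_inv %*% X)
  gls_b <- drop(gls_V %*% t(X) %*% Sigma_inv %*% y)
  m <- joint_meta_2df(betas, Vs)
  expect_equal(m$beta, gls_b, tolerance = 1e-10)
  expect_equal(m$V, gls_V, tolerance = 1e-10)
})

test_that("genomic lambda recovers scale and is calibrated under the null", {
  set.seed(33)
  x <- rchisq(10000, 1)
  expect_equal(genomic_lambda(1.5 * x, 1), 1.5, tolerance = 0.05)
  lam_null <- genomic_lambda(runif(10000), 1, from_p = TRUE)
  expect_true(lam_null > 0.95 && lam_null < 1.05)
  expect_equal(genomic_lambda(rep(qchisq(0.5, 1), 200), 1), 1)
  expect_warning(l <- genomic_lambda(rchisq(10, 1), 1), "lambda fixed at 1")
  expect_equal(l, 1)
})

test_that("GC correction inflates SEs by sqrt(lambda), never deflates, and is monotone", {
  tab <- make_sumstats(50, seed = 34)
  # make the stored p-values consistent with the betas they summarize
  for (f in list(c("BETA_MARG", "SE_MARG", "P_MARG"),
                 c("BETA_MAIN", "SE_MAIN", "P_MAIN"),
                 c("BETA_INT", "SE_INT", "P_INT")))
    tab[[f[3]]] <- wald_1df(tab[[f[1]]], tab[[f[2]]])$p
  tab$CHISQ_JOINT <- qchisq(tab$P_JOINT, 2, lower.tail = FALSE)
  same <- gc_correct(tab, list(marg = 1, main = 1, int = 1, joint = 1))
  expect_equal(same$SE_INT, tab$SE_INT)
  expect_equal(same$P_INT, tab$P_INT)
  corr <- gc_correct(tab, list(marg = 1, main = 1, int = 4, joint = 2))
  expect_equal(corr$SE_INT, 2 * tab$SE_INT)
  expect_equal(abs(corr$BETA_INT / corr$SE_INT),
               abs(tab$BETA_INT / tab$SE_INT) / 2)
  expect_true(all(corr$P_INT >= tab$P_INT))
  expect_true(all(corr$P_JOINT >= tab$P_JOINT))
  defl <- gc_correct(tab, list(marg = 0.5, main = 0.5, int = 0.5, joint = 0.5))
  expect_equal(defl$SE_INT, tab$SE_INT)
})

test_that("GC correction commutes with allele flipping", {
  tab <- make_sumstats(30, seed = 35)
  tab$CHISQ_JOINT <- qchisq(tab$P_JOINT, 2, lower.tail = FALSE)
  lam <- list(marg = 1.2, main = 1.1, int = 1.4, joint = 1.3)
  flip <- function(t) {
    t <- data.table::copy(t)
    for (bc in c("BETA_MARG", "BETA_MAIN", "BETA_INT")) t[[bc]] <- -t[[bc]]
    t$EAF <- 1 - t$EAF
    t
  }
  expect_equal(flip(gc_correct(tab, lam)), gc_correct(flip(tab), lam))
})

test_that("population meta reduces correctly for identical and partial cohorts", {
  tb <- make_sumstats(20, seed = 36)
  # K = 4 identical cohorts: pooled interaction se is halved
  m4 <- population_meta(list(a = tb, b = tb, c = tb, d = tb), gc = FALSE)
  i <- match(tb$SNPID, m4$SNPID)
  expect_equal(m4$SE_INT[i], tb$SE_INT / 2, tolerance = 1e-12)
  expect_equal(m4$BETA_INT[i], tb$BETA_INT, tolerance = 1e-12)
  expect_equal(m4$SE_MAIN_2DF[i], tb$SE_MAIN / 2, tolerance = 1e-10)
  expect_true(all(m4$K_COHORTS == 4))
  expect_true(all(m4$DIRECTIONS %in% c("++++", "----")))
  # single cohort: meta equals the cohort (no GC below the lambda floor)
  m1 <- suppressWarnings(population_meta(list(only = tb), gc = TRUE))
  i1 <- match(tb$SNPID, m1$SNPID)
  expect_equal(m1$BETA_INT[i1], tb$BETA_INT)
  expect_equal(m1$SE_INT[i1], tb$SE_INT)
  # variant observed in 2 of 3 cohorts is pooled over those 2
  short <- tb[1:10]
  m23 <- population_meta(list(a = tb, b = tb, c = short), gc = FALSE)
  expect_equal(m23$K_COHORTS[match(tb$SNPID[15], m23$SNPID)], 2)
  expect_equal(m23$K_COHORTS[match(tb$SNPID[5], m23$SNPID)], 3)
  # pooled SE never exceeds the smallest cohort SE
  expect_true(all(m23$SE_INT <= tb$SE_INT[match(m23$SNPID, tb$SNPID)] + 1e-12))
})

test_that("cross-population meta pools group estimates with a second GC pass", {
  g1 <- make_meta_table(15, seed = 37)
  g2 <- data.table::copy(g1)
  # equal estimates in two groups: beta unchanged, se shrinks by sqrt(2)
  cp <- cross_population_meta(list(EUR = g1, AFR = g2), gc = FALSE)
  i <- match(g1$SNPID, cp$SNPID)
  expect_equal(cp$BETA_INT[i], g1$BETA_INT)
  expect_equal(cp$SE_INT[i], g1$SE_INT / sqrt(2), tolerance = 1e-12)
  expect_equal(cp$K_COHORTS[i], g1$K_COHORTS + g2$K_COHORTS)
  # opposite-sign equal-weight groups cancel
  g3 <- data.table::copy(g1)
  g3$BETA_INT <- -g1$BETA_INT
  g3$BETA_INT_2DF <- -g1$BETA_INT_2DF
  cp0 <- cross_population_meta(list(EUR = g1, AFR = g3), gc = FALSE)
  expect_equal(cp0$BETA_INT[match(g1$SNPID, cp0$SNPID)],
               rep(0, 15), tolerance = 1e-12)
})

test_that("allele-frequency QC flags discrepancies and clears after alignment", {
  tb <- make_sumstats(3, seed = 38)
  tb$EAF <- c(0.50, 0.50, 0.50)
  ref <- data.frame(SNPID = tb$SNPID, AF_REF = c(0.10, 0.45, NA))
  q <- suppressMessages(qc_allele_freq(tb, ref))
  expect_identical(q$AF_FLAG, c(TRUE, FALSE, NA))
  # a flipped cohort is flagged before alignment, clean after
  aa <- make_sumstats(2, seed = 39)
  aa$EA <- c("A", "C"); aa$OA <- c("G", "T"); aa$EAF <- c(0.85, 0.4)
  bb <- data.table::copy(aa)
  bb$EA[1] <- "G"; bb$OA[1] <- "A"; bb$EAF[1] <- 0.15
  ref2 <- data.frame(SNPID = aa$SNPID, AF_REF = aa$EAF)
  expect_true(qc_allele_freq(bb, ref2)$AF_FLAG[1])
  al <- align_alleles(list(aa, bb))[[2]]
  expect_false(qc_allele_freq(al, ref2)$AF_FLAG[1])
})
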