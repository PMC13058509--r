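# ROC/AUROC, cutoffs, DeLong, agreement statistics, group tests and the
# sample-size projection, each checked against independent oracles.

test_that("AUROC equals the brute-force concordant-pair fraction", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auroc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auroc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 1, 0))$auroc, 0.5)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(1:12, n, replace = TRUE)  # forces heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(roc_auc(scores, labels)$auroc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC curve sensitivity is nonincreasing and the CI brackets the AUROC", {
  set.seed(33)
  r <- roc_auc(rnorm(80), rbinom(80, 1, 0.5))
  expect_true(all(diff(r$curve$sens) <= 1e-12))
  expect_gte(r$auroc, r$ci95[1])
  expect_lte(r$auroc, r$ci95[2])
})

test_that("cutoff selection matches exhaustive threshold enumeration", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  cc <- choose_cutoff(r, "youden")
  expect_equal(cc$cutoff, 2)              # J ties at 2 and 4; lowest wins
  expect_equal(cc$sens + cc$spec - 1, 0.5)

  rp <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  cp <- choose_cutoff(rp, "youden")
  expect_equal(cp$cutoff, 3)              # minimum positive-class score
  expect_equal(c(cp$sens, cp$spec), c(1, 1))

  cf <- choose_cutoff(rp, "fixed_sens", q = 1.0)
  expect_lte(cf$cutoff, 3)
  expect_equal(cf$npv, 1)                 # FN = 0 forces NPV 1

  # randomized agreement with an independent exhaustive search
  set.seed(35)
  for (rep in 1:10) {
    scores <- round(rnorm(40), 1)
    labels <- rbinom(40, 1, 0.5)
    if (sum(labels) %in% c(0, 40)) next
    r2 <- roc_auc(scores, labels)
    cc2 <- choose_cutoff(r2, "youden")
    cand <- sort(unique(scores))
    j <- vapply(cand, function(ct) {
      mean(scores[labels == 1] >= ct) + mean(scores[labels == 0] < ct) - 1
    }, numeric(1))
    expect_equal(cc2$cutoff, cand[which.max(j)])
    expect_equal(cc2$sens + cc2$spec - 1, max(j), tolerance = 1e-12)
  }
})

test_that("published-table confusion arithmetic reproduces the printed PPV/NPV", {
  s3 <- confusion_from_rates(1.00, 0.54, 29, 107)
  expect_equal(round(s3$ppv, 2), 0.37)
  expect_equal(round(s3$npv, 2), 1.00)
  f1 <- confusion_from_rates(0.89, 0.67, 123, 15)
  expect_equal(round(f1$ppv, 2), 0.96)
  perfect <- confusion_from_rates(1, 1, 10, 10)
  expect_equal(c(perfect$ppv, perfect$npv), c(1, 1))
})

test_that("paired DeLong is degenerate for identical or monotone-equivalent scores", {
  set.seed(37)
  s <- rnorm(60); lab <- rbinom(60, 1, 0.5)
  d1 <- delong_paired(s, s, lab)
  expect_equal(c(d1$z, d1$p), c(0, 1))
  expect_true(d1$degenerate)
  d2 <- delong_paired(s, exp(s) + 3, lab)   # monotone transform, same ranks
  expect_equal(d2$auroc_a, d2$auroc_b)
  expect_equal(d2$p, 1)
})

test_that("DeLong variance agrees with a paired bootstrap", {
  set.seed(39)
  n <- 100
  lab <- rbinom(n, 1, 0.4)
  a <- rnorm(n) + 1.1 * lab        # built-in AUROC gap
  b <- 0.6 * a + rnorm(n, sd = 0.9) + 0.45 * lab
  dl <- delong_paired(a, b, lab)
  boots <- replicate(2000, {
    i <- sample(n, replace = TRUE)
    if (sum(lab[i]) %in% c(0, n)) return(NA_real_)
    rank_auc(a[i], lab[i]) -
      rank_auc(b[i], lab[i])
  })
  boot_var <- var(boots, na.rm = TRUE)
  dl_var <- (dl$delta / dl$z)^2
  expect_lt(abs(dl_var - boot_var) / boot_var, 0.15)
  boot_p <- 2 * pnorm(-abs(dl$delta) / sqrt(boot_var))
  expect_lt(abs(dl$p - boot_p) / max(boot_p, 1e-6), 0.5)
})

test_that("Bland-Altman reproduces closed forms and is antisymmetric", {
  ba <- bland_altman(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ba$bias, 2)
  expect_equal(c(ba$loa_lo, ba$loa_hi), c(2 - 1.96, 2 + 1.96))
  shift <- bland_altman(1:5, 1:5 + 2)
  expect_equal(shift$bias, 2)
  expect_equal(shift$loa_lo, shift$loa_hi)   # zero SD
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("ICC(A,1) penalises bias, is 1 on identity and near 0 under the null", {
  x <- as.numeric(1:20)
  expect_equal(icc_agreement(x, x), 1)
  shifted <- icc_agreement(x, x + 4)
  expect_lt(shifted, 1)
  expect_lt(shifted, cor(x, x + 4))
  set.seed(43)
  expect_lt(abs(icc_agreement(rnorm(500), rnorm(500))), 0.1)
  expect_warning(icc_agreement(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("association returns correlations, regression and rank statistics", {
  a <- association(1:10, 2 * (1:10))
  expect_equal(c(a$pearson_r, a$slope, a$r2), c(1, 2, 1))
  expect_equal(association(c(1, 2, 3), c(1, 3, 2))$spearman_rs, 0.5)
  set.seed(45)
  x <- rnorm(40); y <- rnorm(40)
  perm <- sample(40)
  expect_equal(association(x, y), association(x[perm], y[perm]),
               tolerance = 1e-12)
  expect_warning(association(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("Kruskal-Wallis H matches the hand-ranked value with Dunn pairs", {
  kw <- group_location_test(c(1, 2, 3, 4, 5, 6), rep(1:3, each = 2))
  expect_equal(kw$H, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7,
               tolerance = 1e-9)
  expect_equal(kw$df, 2)
  expect_equal(nrow(kw$pairwise), 3)
  # identical distributions: H = 0
  expect_equal(group_location_test(rep(2, 9), rep(1:3, each = 3))$H, 0)
  # relabeling group order leaves H unchanged
  v <- c(4, 7, 1, 9, 3, 8, 2, 6, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  g2 <- factor(g, levels = c("c", "a", "b"))
  expect_equal(group_location_test(v, g)$H, group_location_test(v, g2)$H)
  expect_error(group_location_test(1:3, rep("a", 3)), "2 groups")
})

test_that("weighted kappa is 1 on agreement, near 0 under independence, <= 0 adversarial", {
  expect_equal(weighted_kappa(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  set.seed(47)
  a <- sample(1:4, 1e4, replace = TRUE)
  b <- sample(1:4, 1e4, replace = TRUE)
  expect_lt(abs(weighted_kappa(a, b)), 0.05)
  expect_lte(weighted_kappa(rep(1, 10), rep(2, 10), n_categories = 2), 0)
  expect_warning(weighted_kappa(rep(1, 5), rep(1, 5), n_categories = 3),
                 "single category")
  # quadratic weights punish distant disagreement harder
  a2 <- c(1, 1, 2, 3, 4, 4, 2, 3)
  b2 <- c(1, 4, 2, 3, 1, 4, 3, 2)
  expect_false(identical(weighted_kappa(a2, b2, weights = "linear"),
                         weighted_kappa(a2, b2, weights = "quadratic")))
})

test_that("Wilcoxon signed-rank handles exact, degenerate and symmetric cases", {
  expect_equal(wilcoxon_signed(1:5, 1:5)$p, 1)
  expect_true(wilcoxon_signed(1:5, 1:5)$degenerate)
  w <- wilcoxon_signed(rep(0, 5), 1:5)
  expect_equal(w$p, 0.0625)               # exact: 2/2^5
  set.seed(49)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(wilcoxon_signed(x, y)$p, wilcoxon_signed(y, x)$p)
})

test_that("the AUROC sample-size solver matches an independent variance solve", {
  n <- samplesize_auroc(0.80, se_target = 0.05, prevalence = 0.30)
  # independent oracle: quadratic in n from the Hanley-McNeil variance
  a <- 0.80; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  f <- function(nn) {
    n1 <- 0.3 * nn; n0 <- 0.7 * nn
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
      (n1 * n0) - 0.05^2
  }
  root <- uniroot(f, c(5, 1e4))$root
  expect_equal(n, ceiling(root))
  expect_equal(n, 112)
  # halving the SE target roughly quadruples n
  n2 <- samplesize_auroc(0.80, se_target = 0.025, prevalence = 0.30)
  expect_equal(n2 / n, 4, tolerance = 0.1)
  # the prevalence sweep has an interior minimum matching the independent
  # variance solve (the Hanley-McNeil variance is asymmetric in prevalence,
  # so the optimum sits above 0.5 for AUROC 0.8)
  grid <- seq(0.1, 0.9, by = 0.05)
  ns <- vapply(grid, function(p) samplesize_auroc(0.8, 0.05, p), numeric(1))
  oracle_ns <- vapply(grid, function(p) {
    g <- function(nn) {
      n1 <- p * nn; n0 <- (1 - p) * nn
      (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
        (n1 * n0) - 0.05^2
    }
    ceiling(uniroot(g, c(5, 1e5))$root)
  }, numeric(1))
  expect_equal(ns, oracle_ns)
  expect_equal(grid[which.min(ns)], grid[which.min(oracle_ns)])
  expect_gt(grid[which.min(ns)], 0.25)
  expect_lt(grid[which.min(ns)], 0.75)
  # CI-width variant reproduces the SE-target call
  expect_equal(samplesize_auroc(0.80, ci_width = 2 * 1.959964 * 0.05,
                                prevalence = 0.30), n)
})

test_that("AUROC and DeLong agree with the field-standard implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  scores <- rnorm(80); lab <- rbinom(80, 1, 0.5)
  ours <- roc_auc(scores, lab)
  ref <- pROC::roc(lab, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(ours$ci95, as.numeric(ci)[c(1, 3)], tolerance = 1e-9)
  b <- 0.5 * scores + rnorm(80)
  ref_b <- pROC::roc(lab, b, quiet = TRUE, direction = "<")
  pr <- pROC::roc.test(ref, ref_b, method = "delong", paired = TRUE)
  ours_p <- delong_paired(scores, b, lab)
  expect_equal(ours_p$p, pr$p.value, tolerance = 1e-9)
})

test_that("statistics are invariant to patient ordering", {
  set.seed(53)
  scores <- rnorm(60); lab <- rbinom(60, 1, 0.5); perm <- sample(60)
  other <- scores + rnorm(60)
  expect_equal(roc_auc(scores, lab)$auroc,
               roc_auc(scores[perm], lab[perm])$auroc)
  expect_equal(delong_paired(scores, other, lab)$p,
               delong_paired(scores[perm], other[perm], lab[perm])$p)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(bland_altman(x, y), bland_altman(x[perm], y[perm]))
  expect_equal(icc_agreement(x, y), icc_agreement(x[perm], y[perm]))
})
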