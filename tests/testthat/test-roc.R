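make_labels <- function(n_pos, n_neg) rep(c("REC", "PTRE"), c(n_pos, n_neg))

test_that("empirical AUC equals brute-force pair counting", {
  # fixed small cases
  r <- empirical_roc(c(3, 1, 2), make_labels(2, 1))
  expect_equal(r$auc, 0.5) # one concordant, one discordant pair
  expect_equal(empirical_roc(c(5, 6, 7, 1, 2), make_labels(3, 2))$auc, 1)
  expect_equal(empirical_roc(rep(4, 6), make_labels(3, 3))$auc, 0.5)
  # property: 150 random tied instances agree with pair counting
  set.seed(42)
  for (i in 1:150) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    s <- sample(0:6, n1 + n0, replace = TRUE)
    lab <- make_labels(n1, n0)
    r <- empirical_roc(s, lab)
    expect_equal(r$auc, auc_bruteforce(s[lab == "REC"], s[lab == "PTRE"]),
                 tolerance = 1e-12)
  }
  expect_error(empirical_roc(1:4, rep("REC", 4)), "both classes")
})

test_that("DeLong variance equals the grouped jackknife oracle", {
  set.seed(7)
  for (i in 1:120) {
    n1 <- sample(3:7, 1); n0 <- sample(3:7, 1)
    s <- round(rnorm(n1 + n0, mean = rep(c(0.8, 0), c(n1, n0))), 1)
    lab <- make_labels(n1, n0)
    r <- empirical_roc(s, lab)
    jk <- jackknife_auc_var(s[lab == "REC"], s[lab == "PTRE"])
    expect_equal(r$auc_se^2, jk, tolerance = 1e-10)
  }
})

test_that("AUC and its DeLong variance agree with pROC", {
  set.seed(8)
  for (i in 1:25) {
    n1 <- sample(4:10, 1); n0 <- sample(4:10, 1)
    s <- round(rnorm(n1 + n0, mean = rep(c(1, 0), c(n1, n0))), 1)
    lab <- make_labels(n1, n0)
    r <- empirical_roc(s, lab)
    pr <- pROC::roc(response = lab, predictor = s, levels = c("PTRE", "REC"),
                    direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$auc_se^2,
                 suppressWarnings(pROC::var(pr, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("the ROC curve itself is a valid staircase", {
  set.seed(9)
  s <- c(rnorm(12, 1), rnorm(9))
  r <- empirical_roc(s, make_labels(12, 9))
  # sensitivities fall and specificities rise with the threshold
  expect_true(all(diff(r$sensitivities) <= 0))
  expect_true(all(diff(r$specificities) >= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("paired DeLong comparison matches jackknife and pROC", {
  set.seed(10)
  for (i in 1:60) {
    n1 <- sample(4:6, 1); n0 <- sample(3:5, 1)
    sa <- round(rnorm(n1 + n0, rep(c(1, 0), c(n1, n0))), 1)
    sb <- round(0.5 * sa + rnorm(n1 + n0), 1)
    lab <- make_labels(n1, n0)
    ra <- empirical_roc(sa, lab); rb <- empirical_roc(sb, lab)
    cmp <- compare_roc(ra, rb, paired = TRUE)
    expect_equal(cmp$auc_diff, ra$auc - rb$auc, tolerance = 1e-12)
    jk <- jackknife_auc_var(sa[lab == "REC"], sa[lab == "PTRE"],
                            sb[lab == "REC"], sb[lab == "PTRE"])
    expect_equal(cmp$se^2, jk, tolerance = 1e-10)
  }
  # one pROC cross-check of the full test
  sa <- c(3, 5, 6, 7, 1, 2, 4); sb <- c(2, 6, 4, 9, 3, 1, 5)
  lab <- make_labels(4, 3)
  cmp <- compare_roc(empirical_roc(sa, lab), empirical_roc(sb, lab))
  pr <- pROC::roc.test(
    pROC::roc(lab, sa, levels = c("PTRE", "REC"), direction = "<", quiet = TRUE),
    pROC::roc(lab, sb, levels = c("PTRE", "REC"), direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pr$p.value, tolerance = 1e-10)
  # identical curves: zero difference, p = 1
  same <- compare_roc(empirical_roc(sa, lab), empirical_roc(sa, lab))
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)
  # unpaired mode: variances add
  rb2 <- empirical_roc(c(4, 6, 1, 2), make_labels(2, 2))
  ra <- empirical_roc(sa, lab)
  un <- compare_roc(ra, rb2, paired = FALSE)
  expect_equal(un$se^2, ra$auc_se^2 + rb2$auc_se^2, tolerance = 1e-12)
  expect_error(compare_roc(ra, rb2, paired = TRUE), "identical subjects")
})

test_that("the Youden cutoff equals the exhaustive-scan optimum", {
  # worked case: REC {3,4,5} vs PTRE {1,2,3}; best J = 2/3, tie broken
  # toward the higher-specificity cutoff between 3 and 4
  r <- empirical_roc(c(3, 4, 5, 1, 2, 3), make_labels(3, 3))
  y <- youden_cutoff(r)
  expect_equal(y$J, 2 / 3, tolerance = 1e-12)
  expect_equal(y$sensitivity, 2 / 3)
  expect_equal(y$specificity, 1)
  expect_gt(y$cutoff, 3); expect_lt(y$cutoff, 4)
  # perfectly separated scores: J = 1 and the cutoff separates the groups
  r <- empirical_roc(c(5, 6, 7, 1, 2), make_labels(3, 2))
  y <- youden_cutoff(r)
  expect_equal(y$J, 1)
  expect_gt(y$cutoff, 2); expect_lt(y$cutoff, 5)
  # all-tied scores: no discrimination
  y <- youden_cutoff(empirical_roc(rep(2, 5), make_labels(3, 2)))
  expect_equal(y$J, 0)
  # property: the maximised J matches an independent epsilon-scan
  set.seed(11)
  for (i in 1:120) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    s <- sample(0:5, n1 + n0, replace = TRUE)
    lab <- make_labels(n1, n0)
    y <- youden_cutoff(empirical_roc(s, lab))
    expect_equal(y$J, youden_max_J_bruteforce(s, lab == "REC"),
                 tolerance = 1e-12)
  }
})

test_that("AUC and Youden J are invariant under monotone transforms", {
  set.seed(12)
  s <- c(rnorm(10, 1), rnorm(8)); lab <- make_labels(10, 8)
  base_auc <- empirical_roc(s, lab)$auc
  base_J <- youden_cutoff(empirical_roc(s, lab))$J
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 100 + 5 * x)) {
    expect_equal(empirical_roc(f(s), lab)$auc, base_auc, tolerance = 1e-12)
    expect_equal(youden_cutoff(empirical_roc(f(s), lab))$J, base_J,
                 tolerance = 1e-12)
  }
})

test_that("the OR-rule envelope matches exhaustive threshold enumeration", {
  # degenerate second marker: envelope reduces to the univariate ROC
  set.seed(13)
  s <- c(rnorm(6, 1), rnorm(5)); lab <- make_labels(6, 5)
  env <- bivariate_roc(s, rep(1, 11), lab, boot = 0)
  expect_equal(env$auc, empirical_roc(s, lab)$auc, tolerance = 1e-12)
  # both markers perfectly separating
  env <- bivariate_roc(c(5, 6, 1, 2), c(9, 8, 3, 2), make_labels(2, 2),
                       boot = 0)
  expect_equal(env$auc, 1)
  # property: 120 random small instances against brute-force enumeration
  # (heavily tied integer scores stress the staircase construction)
  for (i in 1:120) {
    n1 <- sample(3:5, 1); n0 <- sample(2:4, 1)
    sa <- sample(0:4, n1 + n0, replace = TRUE)
    sb <- sample(0:4, n1 + n0, replace = TRUE)
    labi <- make_labels(n1, n0)
    env <- bivariate_roc(sa, sb, labi, boot = 0)
    expect_equal(env$auc,
                 envelope_auc_bruteforce(sa, sb, labi == "REC"),
                 tolerance = 1e-12)
  }
  # envelope dominance over both univariate curves (tie-free scores: a
  # deterministic OR rule cannot replicate the 1/2 credit of tied pairs)
  for (i in 1:40) {
    n1 <- sample(4:7, 1); n0 <- sample(3:6, 1)
    sa <- rnorm(n1 + n0, rep(c(1, 0), c(n1, n0)))
    sb <- rnorm(n1 + n0, rep(c(1, 0), c(n1, n0)))
    labi <- make_labels(n1, n0)
    env <- bivariate_roc(sa, sb, labi, boot = 0)
    expect_gte(env$auc + 1e-12, empirical_roc(sa, labi)$auc)
    expect_gte(env$auc + 1e-12, empirical_roc(sb, labi)$auc)
  }
  # bootstrap SE is seeded and reproducible
  sb <- 0.3 * s + rnorm(11)
  env1 <- bivariate_roc(s, sb, lab, boot = 200, boot_seed = 4)
  env2 <- bivariate_roc(s, sb, lab, boot = 200, boot_seed = 4)
  expect_equal(env1$auc_se, env2$auc_se)
  expect_false(is.na(env1$auc_se))
})

test_that("the OR rule dominates its components in sensitivity only", {
  set.seed(14)
  for (i in 1:60) {
    n <- 20
    tbr <- rnorm(n, rep(c(3, 2), each = n / 2), 1)
    adc <- rnorm(n, rep(c(1300, 1030), each = n / 2), 250)
    lab <- rep(c("REC", "PTRE"), each = n / 2)
    pred_or <- ifelse(tbr > 2 | adc > 1254, "REC", "PTRE")
    pred_t <- ifelse(tbr > 2, "REC", "PTRE")
    pred_a <- ifelse(adc > 1254, "REC", "PTRE")
    d_or <- diagnostic_measures(pred_or, lab)
    d_t <- diagnostic_measures(pred_t, lab)
    d_a <- diagnostic_measures(pred_a, lab)
    expect_gte(d_or$sensitivity, max(d_t$sensitivity, d_a$sensitivity))
    expect_lte(d_or$specificity, min(d_t$specificity, d_a$specificity))
  }
})
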