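test_that("ROC handles perfect separation and label inversion", {
  scores <- c(a = -3, b = -2.5, c = -2, d = 1, e = 1.5, f = 2)
  labels <- c(a = TRUE, b = TRUE, c = TRUE, d = FALSE, e = FALSE, f = FALSE)
  roc <- roc_and_youden(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_j, 1)
  expect_true(roc$youden_cutoff > -2 && roc$youden_cutoff < 1)
  inv <- roc_and_youden(scores, !labels)
  expect_equal(inv$auc, 0)
  expect_error(roc_and_youden(scores, rep(TRUE, 6)), "both")
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(19)
  n <- 200
  scores <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)  # heavy ties
  labels <- runif(n) < 0.4
  roc <- roc_and_youden(scores, labels)
  expect_equal(roc$auc, brute_auc_mw(scores, labels), tolerance = 1e-12)
  # no ties: AUC(scores) + AUC(-scores) = 1 for fixed labels
  sc2 <- rnorm(n)
  a1 <- roc_and_youden(sc2, labels)$auc
  a2 <- roc_and_youden(-sc2, labels)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ref <- pROC::roc(labels, scores, direction = ">", quiet = TRUE)  # low = positive
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("confusion at the Youden cutoff reproduces the maximal J", {
  set.seed(23)
  scores <- rnorm(120)
  labels <- runif(120) < plogis(-1.5 * scores)
  roc <- roc_and_youden(scores, labels)
  cf <- classify_and_confuse(scores, roc$youden_cutoff, labels)
  j <- cf$tp / (cf$tp + cf$fn) + cf$tn / (cf$tn + cf$fp) - 1
  expect_equal(j, roc$youden_j, tolerance = 1e-12)
})

test_that("confusion metrics follow the printed-percentage arithmetic", {
  # 38 of 53 responders low, 61 of 67 non-responders high (n = 120)
  scores <- c(rep(-1, 38), rep(1, 15), rep(1, 61), rep(-1, 6))
  labels <- rep(c(TRUE, FALSE), c(53, 67))
  cf <- classify_and_confuse(scores, 0, labels)
  expect_equal(c(cf$tp, cf$fn, cf$tn, cf$fp), c(38, 15, 61, 6))
  expect_identical(cf$sensitivity, 71.7)
  expect_identical(cf$specificity, 91.0)
  expect_identical(cf$accuracy, 82.5)
  expect_equal(cf$orr_by_group[["low"]], 38 / 44)
  expect_equal(cf$orr_by_group[["high"]], 15 / 76)
  # everyone predicted positive
  cf2 <- classify_and_confuse(rep(-1, 10), 0, rep(c(TRUE, FALSE), 5))
  expect_identical(cf2$sensitivity, 100)
  expect_identical(cf2$specificity, 0)
})

test_that("KM curves match hand product-limit computations", {
  cv <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$survival, c(2/3, 1/3, 0))
  cv2 <- km_curve(c(4, 8, 2), c(0, 0, 0))
  expect_true(all(cv2$survival == 1))
  # duplicate event times collapse into one step with d > 1
  cv3 <- km_curve(c(1, 1, 2, 2, 3), c(1, 1, 1, 0, 1))
  expect_equal(cv3$time, c(1, 2, 3))
  expect_equal(cv3$n_event, c(2, 1, 1))
  expect_equal(cv3$survival, c(3/5, 3/5 * 2/3, 0))
})

test_that("group survival comparison reports log-rank, HR, and medians coherently", {
  # identical groups
  ids <- sprintf("s%02d", 1:20)
  cl <- data.frame(sample_id = ids, os_time = rep(c(3, 6, 9, 12, 15), 4),
                   os_event = rep(c(1L, 0L, 1L, 1L, 0L), 4),
                   pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  s <- setNames(rep(c(-1, 1), each = 10), ids)
  res <- compare_survival(s, cl, cutoff = 0)
  expect_equal(res$logrank_p, 1)
  expect_true(res$hr_ci[["lower"]] <= 1 && res$hr_ci[["upper"]] >= 1)
  # same implementation as the screening log-rank
  direct <- logrank_test(cl$os_time, cl$os_event, as.integer(s > 0))
  expect_identical(res$logrank_p, direct$p_value)

  # planted HR = 3, n = 300
  set.seed(41)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.03 * exp(log(3) * g))
  cns <- rexp(n, 0.01)
  ids2 <- sprintf("t%03d", 1:n)
  cl2 <- data.frame(sample_id = ids2, os_time = pmin(t, cns),
                    os_event = as.integer(t <= cns),
                    pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  res2 <- compare_survival(setNames(g, ids2), cl2, cutoff = 0.5)
  expect_gt(res2$hazard_ratio, 2.2)
  expect_lt(res2$hazard_ratio, 4.1)

  # median undefined when the curve never reaches 0.5
  cl3 <- data.frame(sample_id = sprintf("u%02d", 1:10),
                    os_time = c(1, rep(20, 9)), os_event = c(1L, rep(0L, 9)),
                    pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  s3 <- setNames(c(rep(-1, 5), rep(1, 5)), cl3$sample_id)
  # one event in one group: coxph warns about a possibly infinite coefficient
  suppressWarnings(res3 <- compare_survival(s3, cl3, cutoff = 0))
  expect_true(is.na(res3$median_survival[["high"]]))
  expect_error(compare_survival(setNames(rep(-1, 10), cl3$sample_id), cl3, cutoff = 0),
               "non-empty")
})

test_that("the survival-driven cutpoint scan is an exhaustive minimum-p search", {
  # bimodal scores, survival differing between modes
  set.seed(47)
  n <- 60
  mode_hi <- rep(c(FALSE, TRUE), each = n / 2)
  s <- ifelse(mode_hi, rnorm(n, 5, 0.3), rnorm(n, 0, 0.3))
  t <- rexp(n, ifelse(mode_hi, 0.2, 0.02))
  ids <- sprintf("s%02d", 1:n)
  cl <- data.frame(sample_id = ids, os_time = t, os_event = 1L,
                   pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  suppressMessages(cp <- os_driven_cutpoint(setNames(s, ids), cl))
  # the chosen split should separate the two score modes
  expect_identical(sort(ids[s <= cp$cutoff]), sort(ids[!mode_hi]))
  # brute-force loop over all admissible cutoffs
  cand <- sort(unique(s))
  brute <- sapply(cand, function(cut) {
    nl <- sum(s <= cut)
    if (nl < 0.1 * n || (n - nl) < 0.1 * n) return(NA_real_)
    logrank_test(t, rep(1L, n), as.integer(s > cut))$p_value
  })
  expect_equal(cp$logrank_p, min(brute, na.rm = TRUE))
  expect_equal(cp$cutoff, cand[which.min(brute)])
  expect_equal(nrow(cp$scan), sum(!is.na(brute)))

  # no admissible split: half-and-half constraint on odd n
  cl21 <- cl[1:21, ]
  expect_error(suppressMessages(
    os_driven_cutpoint(setNames(s[1:21], ids[1:21]), cl21, min_group_fraction = 0.5)),
    "no admissible")
})

test_that("fixed-effect meta-analysis matches the inverse-variance formulas", {
  single <- meta_fixed_effect(log(2.5), 0.3)
  expect_equal(single$pooled_log_hr, log(2.5))
  expect_equal(single$q_statistic, 0)
  expect_equal(single$i_squared, 0)

  ident <- meta_fixed_effect(rep(log(3), 3), c(0.2, 0.3, 0.4))
  expect_equal(ident$pooled_hr, 3)
  expect_equal(ident$i_squared, 0)

  # hand computation: w = (25, 6.25)
  m <- meta_fixed_effect(c(log(2), log(4)), c(0.2, 0.4))
  mu <- (25 * log(2) + 6.25 * log(4)) / 31.25
  expect_equal(m$pooled_log_hr, mu, tolerance = 1e-14)
  expect_equal(m$pooled_se, 1 / sqrt(31.25), tolerance = 1e-14)
  expect_equal(m$q_statistic, 25 * (log(2) - mu)^2 + 6.25 * (log(4) - mu)^2,
               tolerance = 1e-14)
  expect_equal(m$hr_ci[["lower"]], exp(mu - 1.96 / sqrt(31.25)), tolerance = 1e-14)
  expect_error(meta_fixed_effect(c(0.1, 0.2), c(0.3, 0)), "standard errors")

  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = c(log(2), log(4)), sei = c(0.2, 0.4), method = "EE")
  expect_equal(m$pooled_log_hr, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m$pooled_se, rma$se, tolerance = 1e-10)
  expect_equal(m$q_statistic, rma$QE, tolerance = 1e-10)
})

test_that("the pooled CI shrinks as studies accumulate", {
  lhr <- c(0.9, 1.1, 0.8, 1.0, 1.2)
  se <- c(0.5, 0.4, 0.6, 0.3, 0.5)
  widths <- sapply(2:5, function(k) {
    m <- meta_fixed_effect(lhr[1:k], se[1:k])
    m$hr_ci[["upper"]] - m$hr_ci[["lower"]]
  })
  ses <- sapply(1:5, function(k) meta_fixed_effect(lhr[1:k], se[1:k])$pooled_se)
  expect_true(all(diff(ses) < 0))
})
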