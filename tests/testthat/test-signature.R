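test_that("unpenalised fit recovers planted coefficients on two candidate pairs", {
  set.seed(33)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  haz <- 0.05 * exp(-1.0 * x1 + 0.5 * x2)
  t <- rexp(n, haz); cns <- rexp(n, 0.01)
  cl <- data.frame(sample_id = ids, os_time = pmin(t, cns),
                   os_event = as.integer(t <= cns),
                   pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  ind <- rbind(`A|B` = x1, `C|D` = x2)
  colnames(ind) <- ids
  sig <- fit_signature(ind, cl, fit_config(seed = 1, mode = "unpenalized"))
  co <- setNames(sig$pairs$coefficient, sig$pairs$label)
  expect_lt(abs(co[["A|B"]] - (-1.0)), 0.25)
  expect_lt(abs(co[["C|D"]] - 0.5), 0.25)
  expect_identical(sig$provenance, "fitted")
})

test_that("refit coefficients sit at a local maximum of the Cox partial likelihood", {
  set.seed(32)
  n <- 150
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  haz <- 0.05 * exp(0.8 * x1 - 0.6 * x2)
  t <- rexp(n, haz)
  ids <- sprintf("s%03d", 1:n)
  cl <- data.frame(sample_id = ids, os_time = t, os_event = 1L,
                   pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  ind <- rbind(`A|B` = x1, `C|D` = x2); colnames(ind) <- ids
  sig <- fit_signature(ind, cl, fit_config(seed = 1, mode = "unpenalized"))
  beta <- sig$pairs$coefficient
  X <- t(ind)
  ll_at <- function(b) {
    survival::coxph(survival::Surv(t, rep(1L, n)) ~ X, ties = "breslow",
                    init = b, control = survival::coxph.control(iter.max = 0))$loglik[2]
  }
  ll0 <- ll_at(beta)
  for (k in seq_along(beta)) for (d in c(-0.05, 0.05)) {
    bp <- beta; bp[k] <- bp[k] + d
    expect_lt(ll_at(bp), ll0)
  }
})

test_that("pure-noise candidates under a strong penalty end in a defined empty selection", {
  set.seed(40)
  n <- 80
  ids <- sprintf("s%03d", 1:n)
  cl <- data.frame(sample_id = ids, os_time = rexp(n, 0.05), os_event = 1L,
                   pfs_time = NA, pfs_event = NA, response = NA, responder = NA)
  ind <- matrix(rbinom(30 * n, 1, 0.5), nrow = 30,
                dimnames = list(sprintf("n%02d|m%02d", 1:30, 1:30), ids))
  expect_error(
    fit_signature(ind, cl, fit_config(seed = 3, mode = "lasso",
                                      lambda_rule = "lambda.1se")),
    class = "irgpi_empty_selection")
})

test_that("the bundled published signature loads verbatim", {
  sig <- load_bundled_signature()
  expect_s3_class(sig, "irgpi_signature")
  expect_identical(sig$provenance, "bundled")
  expect_equal(nrow(sig$pairs), 31L)
  co <- setNames(sig$pairs$coefficient, sig$pairs$label)
  expect_identical(unname(co["CD1B|AMHR2"]), -0.133719837)
  expect_identical(unname(co["IFNG|NTS"]), -0.208747404)
  expect_identical(unname(co["SFTPD|CR2"]), 0.248588976)
  # recurring genes are kept as published, no dedup
  expect_equal(sum(sig$pairs$gene_a == "IDO1"), 2L)
  expect_equal(sum(sig$pairs$gene_b == "IL1R1"), 3L)
  expect_equal(attr(sig, "n_genes"),
               length(unique(c(sig$pairs$gene_a, sig$pairs$gene_b))))
})

test_that("the index is the plain dot product of indicators and coefficients", {
  sig <- load_bundled_signature()
  k <- nrow(sig$pairs)
  set.seed(12)
  ind <- matrix(rbinom(k * 6, 1, 0.5), nrow = k,
                dimnames = list(sig$pairs$label, sprintf("s%d", 1:6)))
  sc <- compute_irgpi(ind, sig)
  for (j in 1:6) {
    expect_equal(sc$irgpi[j], sum(ind[, j] * sig$pairs$coefficient), tolerance = 1e-15)
  }
  # single active pair reproduces its printed coefficient
  ind1 <- matrix(0L, nrow = k, ncol = 1, dimnames = list(sig$pairs$label, "s1"))
  ind1["CD1B|AMHR2", 1] <- 1L
  expect_equal(compute_irgpi(ind1, sig)$irgpi, -0.133719837)
  # empty sum
  ind0 <- ind1; ind0[] <- 0L
  expect_equal(compute_irgpi(ind0, sig)$irgpi, 0)
})

test_that("scores always lie within the analytic coefficient bounds", {
  sig <- load_bundled_signature()
  bounds <- irgpi_bounds(sig)
  genes <- unique(c(sig$pairs$gene_a, sig$pairs$gene_b))
  set.seed(77)
  expr <- matrix(rexp(length(genes) * 40), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%02d", 1:40)))
  sc <- score_cohort_from_expression(expr, sig)
  expect_true(all(sc$irgpi >= bounds["lower"] - 1e-12))
  expect_true(all(sc$irgpi <= bounds["upper"] + 1e-12))
})

test_that("expression scoring is invariant to per-sample monotone transforms and order", {
  sig <- load_bundled_signature()
  genes <- unique(c(sig$pairs$gene_a, sig$pairs$gene_b))
  set.seed(78)
  expr <- matrix(rexp(length(genes) * 15) + 0.01, nrow = length(genes),
                 dimnames = list(genes, sprintf("s%02d", 1:15)))
  s1 <- score_cohort_from_expression(expr, sig)
  s2 <- score_cohort_from_expression(monotone_distort(expr, seed = 2), sig)
  expect_identical(s1, s2)
  # per-sample quantile transform = rank map, also monotone
  qt <- apply(expr, 2, function(x) qnorm(rank(x) / (length(x) + 1)) + 10)
  rownames(qt) <- rownames(expr)
  expect_identical(score_cohort_from_expression(qt, sig), s1)
  perm <- sample(ncol(expr))
  s3 <- score_cohort_from_expression(expr[, perm], sig)
  # BLAS may regroup the dot-product sums when columns move, so tolerance-equal
  expect_equal(s3$irgpi[match(s1$sample_id, s3$sample_id)], s1$irgpi,
               tolerance = 1e-12)
})

test_that("missing signature genes follow the declared policy", {
  sig <- load_bundled_signature()
  genes <- setdiff(unique(c(sig$pairs$gene_a, sig$pairs$gene_b)), "IFNG")
  set.seed(79)
  expr <- matrix(rexp(length(genes) * 4), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%d", 1:4)))
  expect_error(score_cohort_from_expression(expr, sig), "IFNG")
  expect_warning(sc <- score_cohort_from_expression(expr, sig, "drop_pair"),
                 "NOT comparable")
  expect_equal(nrow(sc), 4L)
  expect_true(all(is.finite(sc$irgpi)))
})

test_that("a single-sample cohort scores by direct pair evaluation", {
  expr <- matrix(c(4, 2, 1, 7), ncol = 1,
                 dimnames = list(c("W", "X", "Y", "Z"), "only"))
  sig <- irgpi_signature(data.frame(gene_a = c("W", "Y"), gene_b = c("X", "Z"),
                                    coefficient = c(0.5, -2)))
  sc <- score_cohort_from_expression(expr, sig)
  expect_equal(sc$irgpi, 0.5 * 1 + (-2) * 0)  # W>X yes, Y>Z no
})

test_that("signature TSV round trip preserves coefficients", {
  sig <- load_bundled_signature()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, p)
  sig2 <- read_signature(p)
  expect_identical(sig2$pairs$coefficient, sig$pairs$coefficient)
  expect_identical(sig2$pairs$label, sig$pairs$label)
})
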