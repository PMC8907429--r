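#' Construct a gene-pair signature object
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` and
#'   `coefficient` (a `label` column is added if absent).
#' @param name Signature name.
#' @param provenance `"fitted"` or `"bundled"`.
#' @return An object of class `irgpi_signature`.
#' @export
irgpi_signature <- function(pairs, name = "signature",
                            provenance = c("fitted", "bundled")) {
  provenance <- match.arg(provenance)
  if (is.null(pairs$label)) pairs$label <- paste0(pairs$gene_a, "|", pairs$gene_b)
  if (anyDuplicated(pairs$label)) stop("duplicated pair labels in signature")
  if (any(pairs$gene_a == pairs$gene_b)) stop("a pair cannot join a gene with itself")
  if (any(!is.finite(pairs$coefficient)) || any(pairs$coefficient == 0)) {
    stop("signature coefficients must be finite and non-zero")
  }
  structure(list(pairs = pairs[, c("gene_a", "gene_b", "label", "coefficient")],
                 name = name, provenance = provenance),
            class = "irgpi_signature")
}

#' @export
print.irgpi_signature <- function(x, ...) {
  cat(sprintf("IRGPI signature '%s' (%s): %d pairs, %d distinct genes\n",
              x$name, x$provenance, nrow(x$pairs),
              length(unique(c(x$pairs$gene_a, x$pairs$gene_b)))))
  lo <- sum(pmin(x$pairs$coefficient, 0))
  hi <- sum(pmax(x$pairs$coefficient, 0))
  cat(sprintf("score range: [%.4f, %.4f]; higher score = higher hazard\n", lo, hi))
  invisible(x)
}

#' Attainable score bounds of a signature
#'
#' Every score is a sum of a 0/1 subset of the coefficients, so it lies in
#' `[sum of negative coefficients, sum of positive coefficients]`.
#'
#' @param model An `irgpi_signature`.
#' @return Numeric `c(lower, upper)`.
#' @export
irgpi_bounds <- function(model) {
  c(lower = sum(pmin(model$pairs$coefficient, 0)),
    upper = sum(pmax(model$pairs$coefficient, 0)))
}

#' Fitting configuration for [fit_signature()]
#'
#' @param seed Required integer seed controlling cross-validation fold
#'   assignment, so fitted signatures are reproducible.
#' @param nfolds Cross-validation folds for the penalised stage.
#' @param lambda_rule `"lambda.min"` (deviance-minimising penalty, default)
#'   or `"lambda.1se"`.
#' @param mode `"auto"` (default: penalised unless candidates are few
#'   relative to events), `"lasso"`, or `"unpenalized"`.
#' @return A list of fitting options.
#' @export
fit_config <- function(seed, nfolds = 10L, lambda_rule = c("lambda.min", "lambda.1se"),
                       mode = c("auto", "lasso", "unpenalized")) {
  if (missing(seed) || !is.numeric(seed)) stop("fit_config() requires a numeric seed")
  list(seed = as.integer(seed), nfolds = as.integer(nfolds),
       lambda_rule = match.arg(lambda_rule), mode = match.arg(mode))
}

#' Fit a multivariate Cox gene-pair signature
#'
#' Default two-stage procedure: (1) an L1-penalised Cox partial-likelihood
#' fit over all candidate pairs, with the penalty chosen by k-fold
#' cross-validated partial-likelihood deviance (fold assignment seeded),
#' keeps the pairs with non-zero coefficients; (2) an unpenalised
#' multivariate Cox refit on the kept pairs yields the final coefficients.
#' When the number of candidates is at most one fifth of the number of
#' events (and `mode = "auto"`), the penalised stage is skipped and a
#' single unpenalised fit is used. Pairs showing separation (monotone
#' likelihood, diverging coefficient) are dropped with a warning and the
#' model refit.
#'
#' @param indicators Pair x sample 0/1 matrix restricted to candidate pairs.
#' @param clinical Clinical data frame from [read_clinical()].
#' @param config Options from [fit_config()]; the seed is mandatory.
#' @param endpoint `"os"` (default) or `"pfs"`.
#' @return An `irgpi_signature` with `provenance = "fitted"`.
#' @export
fit_signature <- function(indicators, clinical, config, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  common <- intersect(colnames(indicators), clinical$sample_id)
  if (length(common) == 0L) stop("no samples shared between indicators and clinical table")
  ind <- indicators[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  time <- if (endpoint == "os") cl$os_time else cl$pfs_time
  event <- if (endpoint == "os") cl$os_event else cl$pfs_event
  ok <- !is.na(time) & !is.na(event)
  ind <- ind[, ok, drop = FALSE]; time <- time[ok]; event <- event[ok]
  if (nrow(ind) < 2L) stop("need at least 2 candidate pairs")
  n_events <- sum(event)
  if (n_events < 10L) stop("need at least 10 events to fit a signature (got ", n_events, ")")

  x <- t(ind)
  labels <- rownames(ind)
  mode <- config$mode
  if (mode == "auto") {
    mode <- if (nrow(ind) <= n_events / 5) "unpenalized" else "lasso"
  }
  if (mode == "lasso") {
    y <- survival::Surv(time, event)
    set.seed(config$seed)
    foldid <- sample(rep(seq_len(config$nfolds), length.out = nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid, alpha = 1)
    beta <- as.numeric(stats::coef(cv, s = config$lambda_rule))
    selected <- labels[beta != 0]
    if (length(selected) == 0L) {
      stop(structure(class = c("irgpi_empty_selection", "error", "condition"),
                     list(message = "penalised fit selected no pairs (all coefficients zero)",
                          call = sys.call())))
    }
  } else {
    selected <- labels
  }

  # unpenalised refit with iterative drop of separated pairs
  repeat {
    xs <- x[, selected, drop = FALSE]
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ xs, ties = "breslow"),
      warning = function(w) {
        if (grepl("infinite|converge|singular", conditionMessage(w))) sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- stats::setNames(as.numeric(fit$coefficients), selected)
    bad <- is.na(coefs) | !is.finite(coefs) | (sep_warn & abs(coefs) > 15)
    if (!any(bad)) break
    warning("dropping ", sum(bad), " pair(s) with separated or inestimable coefficients: ",
            paste(selected[bad], collapse = ", "))
    selected <- selected[!bad]
    if (length(selected) == 0L) stop("no estimable pairs left after dropping separated ones")
  }
  coefs <- coefs[coefs != 0]
  if (length(coefs) == 0L) stop("all refit coefficients are zero")
  pr <- attr(indicators, "pairs")
  if (is.null(pr)) {
    sp <- strsplit(names(coefs), "|", fixed = TRUE)
    pr <- data.frame(gene_a = vapply(sp, `[`, "", 1L),
                     gene_b = vapply(sp, `[`, "", 2L),
                     label = names(coefs), stringsAsFactors = FALSE)
  } else {
    pr <- pr[match(names(coefs), pr$label), c("gene_a", "gene_b", "label")]
  }
  pr$coefficient <- unname(coefs)
  out <- irgpi_signature(pr, name = "fitted_signature", provenance = "fitted")
  out$fit <- list(mode = mode, n = length(time), n_events = n_events,
                  seed = config$seed, loglik = fit$loglik)
  out
}

#' Compute per-sample IRGPI scores from a pair-indicator matrix
#'
#' The immune-related gene-pair index of a sample is the weighted sum of its
#' pair indicators, \eqn{\mathrm{IRGPI}(s) = \sum_i \mathrm{score}_i(s)
#' \cdot \beta_i}. Higher scores indicate higher hazard / lower chance of
#' response.
#'
#' @param indicators Pair x sample 0/1 matrix containing the model's pairs.
#' @param model An `irgpi_signature`.
#' @param missing_policy `"error"` (default) or `"drop_pair"`: silently
#'   unscoreable pairs are excluded from the sum, with a prominent warning
#'   that the resulting scores are not comparable to published cutoffs.
#' @return A data frame with columns `sample_id`, `irgpi`.
#' @export
compute_irgpi <- function(indicators, model, missing_policy = c("error", "drop_pair")) {
  missing_policy <- match.arg(missing_policy)
  want <- model$pairs$label
  have <- want %in% rownames(indicators)
  if (!all(have)) {
    if (missing_policy == "error") {
      stop("signature pair(s) absent from indicator matrix: ",
           paste(want[!have], collapse = ", "))
    }
    warning(sum(!have), " of ", length(want), " signature pairs dropped; ",
            "scores are NOT comparable to published cutoffs", immediate. = TRUE)
  }
  used <- want[have]
  if (length(used) == 0L) stop("no signature pairs scoreable")
  coefs <- model$pairs$coefficient[match(used, model$pairs$label)]
  score <- as.numeric(crossprod(indicators[used, , drop = FALSE], coefs))
  data.frame(sample_id = colnames(indicators), irgpi = score,
             stringsAsFactors = FALSE)
}

#' Score a cohort directly from expression
#'
#' Computes indicators for exactly the model's pairs, then the weighted sum
#' ([compute_irgpi()]). Because the indicators depend only on within-sample
#' expression order, the scores are invariant to per-sample monotone
#' transformations by construction.
#'
#' @param expr Genes x samples numeric matrix.
#' @inheritParams compute_irgpi
#' @return A data frame with columns `sample_id`, `irgpi`.
#' @export
score_cohort_from_expression <- function(expr, model,
                                         missing_policy = c("error", "drop_pair")) {
  missing_policy <- match.arg(missing_policy)
  pr <- model$pairs
  scoreable <- pr$gene_a %in% rownames(expr) & pr$gene_b %in% rownames(expr)
  if (!all(scoreable) && missing_policy == "error") {
    miss <- setdiff(unique(c(pr$gene_a, pr$gene_b)), rownames(expr))
    stop("signature gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  }
  ind <- compute_pair_indicators(expr, pr[scoreable, , drop = FALSE])
  compute_irgpi(ind, model, missing_policy)
}

#' Load the bundled published 31-pair melanoma signature
#'
#' Returns the published immune-related gene-pair signature for melanoma
#' immune-checkpoint-inhibitor response (31 pairs with multivariate Cox
#' coefficients at full printed precision). Pairs reusing a gene are kept
#' exactly as published; no deduplication is applied. The file checksum is
#' verified at load.
#'
#' @return An `irgpi_signature` with `provenance = "bundled"`; the number of
#'   distinct genes is available via `attr(, "n_genes")`.
#' @export
load_bundled_signature <- function() {
  path <- system.file("extdata", "published_signature_31pairs.tsv",
                      package = "irgpi", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, BUNDLED_SIGNATURE_MD5)) {
    stop("bundled signature file is corrupted (checksum mismatch)")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  out <- irgpi_signature(tab, name = "published_melanoma_31pair",
                         provenance = "bundled")
  attr(out, "n_genes") <- length(unique(c(tab$gene_a, tab$gene_b)))
  out
}

# md5 of inst/extdata/published_signature_31pairs.tsv, fixed at packaging time
BUNDLED_SIGNATURE_MD5 <- "410b9102aca92d86b50b202fc671cab3"

#' Write a signature as TSV
#' @param model An `irgpi_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(model, path) {
  utils::write.table(
    data.frame(gene_a = model$pairs$gene_a, gene_b = model$pairs$gene_b,
               coefficient = format(model$pairs$coefficient, digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature from TSV
#' @param path Path to a TSV with columns `gene_a`, `gene_b`, `coefficient`.
#' @param name Signature name.
#' @return An `irgpi_signature` with `provenance = "fitted"`.
#' @export
read_signature <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  irgpi_signature(tab, name = name, provenance = "fitted")
}
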