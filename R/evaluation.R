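# Coerce a ScoreTable (data.frame sample_id/irgpi), a named numeric vector,
# or a bare numeric vector into a (possibly named) numeric vector.
as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("sample_id", "irgpi") %in% names(scores))) {
      stop("score table must have columns sample_id and irgpi")
    }
    return(stats::setNames(scores$irgpi, scores$sample_id))
  }
  if (!is.numeric(scores)) stop("scores must be numeric")
  scores
}

# Align scores and labels; labels may be named or positional.
align_labels <- function(s, labels) {
  if (!is.null(names(labels)) && !is.null(names(s))) {
    labels <- labels[names(s)]
  }
  if (length(labels) != length(s)) stop("scores and labels have different lengths")
  as.logical(labels)
}

#' ROC curve and maximum-Youden cutoff
#'
#' Thresholds are the midpoints between consecutive distinct scores plus
#' -Inf/+Inf sentinels. Under the default direction (`low_is_positive`: a
#' low index predicts response) a sample is called positive when its score
#' is at or below the threshold. AUC is the trapezoidal area under the
#' (1 - specificity, sensitivity) curve, which equals the tie-corrected
#' Mann-Whitney probability. The Youden cutoff maximises
#' J = sensitivity + specificity - 1; ties are broken toward higher
#' sensitivity, then the lower threshold.
#'
#' @param scores Score table from [compute_irgpi()] or a (named) numeric
#'   vector.
#' @param labels Logical responder flags (TRUE = CR/PR), named or in score
#'   order.
#' @param direction `"low_is_positive"` (default) or `"high_is_positive"`.
#' @return A list of class `irgpi_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_cutoff`, `youden_j`, `direction`.
#' @export
roc_and_youden <- function(scores, labels,
                           direction = c("low_is_positive", "high_is_positive")) {
  direction <- match.arg(direction)
  s <- as_score_vector(scores)
  y <- align_labels(s, labels)
  if (anyNA(y) || anyNA(s)) stop("missing scores or labels")
  if (length(unique(y)) < 2L) stop("both responder and non-responder samples are required")
  flip <- direction == "high_is_positive"
  sw <- if (flip) -s else s
  d <- sort(unique(sw))
  thr <- c(-Inf, if (length(d) > 1L) (d[-1L] + d[-length(d)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(sw[y] <= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sw[!y] > t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  best <- best[1L]  # thresholds ascending: first = lowest threshold
  structure(list(thresholds = if (flip) -thr else thr,
                 sensitivity = sens, specificity = spec, auc = auc,
                 youden_cutoff = if (flip) -thr[best] else thr[best],
                 youden_j = j[best], direction = direction),
            class = "irgpi_roc")
}

#' @export
print.irgpi_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, Youden cutoff = %.4g (J = %.3f), direction = %s\n",
              x$auc, x$youden_cutoff, x$youden_j, x$direction))
  invisible(x)
}

#' Dichotomise scores at a cutoff and tabulate classification
#'
#' The low group contains samples with score at or below the cutoff. Under
#' the default direction the low group is predicted responder (CR/PR).
#' Percentages are reported to one decimal.
#'
#' @param scores Score table or (named) numeric vector.
#' @param cutoff Finite score threshold.
#' @param labels Logical responder flags.
#' @param direction `"low_is_positive"` (default) or `"high_is_positive"`.
#' @return A list of class `irgpi_confusion`: counts `tp`, `fn`, `tn`,
#'   `fp`; `sensitivity`, `specificity`, `accuracy` (percent, one decimal);
#'   `orr_by_group` (responder fraction in the low and high group);
#'   `group` (the per-sample low/high assignment).
#' @export
classify_and_confuse <- function(scores, cutoff, labels,
                                 direction = c("low_is_positive", "high_is_positive")) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  s <- as_score_vector(scores)
  y <- align_labels(s, labels)
  low <- s <= cutoff
  pred_pos <- if (direction == "low_is_positive") low else !low
  tp <- sum(pred_pos & y); fn <- sum(!pred_pos & y)
  tn <- sum(!pred_pos & !y); fp <- sum(pred_pos & !y)
  grp <- ifelse(low, "low", "high")
  orr <- c(low = if (any(low)) mean(y[low]) else NA_real_,
           high = if (any(!low)) mean(y[!low]) else NA_real_)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = round(100 * tp / (tp + fn), 1),
                 specificity = round(100 * tn / (tn + fp), 1),
                 accuracy = round(100 * (tp + tn) / length(s), 1),
                 orr_by_group = orr,
                 group = stats::setNames(grp, names(s))),
            class = "irgpi_confusion")
}

#' @export
print.irgpi_confusion <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Kaplan-Meier product-limit curve
#'
#' Wraps `survival::survfit`. Multiple events at one time form a single
#' step; censored subjects leave the risk set after their time.
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Data frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Compare survival between score-defined groups
#'
#' Splits samples into low (score at or below cutoff) and high groups, then
#' reports Kaplan-Meier curves per group, the log-rank p-value (same
#' implementation as the screening test), the Cox hazard ratio of high
#' versus low with a Wald 95% CI (Breslow tie handling), and median
#' survival per group (NA when the curve never reaches 0.5).
#'
#' Alternatively pass a ready-made group assignment as `groups` (values
#' `"low"`/`"high"` or 0/1, named by sample) and omit `cutoff`.
#'
#' @param scores Score table or named numeric vector (ignored when `groups`
#'   is given).
#' @param clinical Clinical data frame from [read_clinical()].
#' @param cutoff Score threshold defining the low group.
#' @param endpoint `"os"` (default) or `"pfs"`.
#' @param groups Optional explicit group assignment.
#' @return A list of class `irgpi_survcomp`: `km` (list of curves),
#'   `logrank_p`, `chi_square`, `hazard_ratio`, `hr_ci`, `median_survival`,
#'   `n`.
#' @export
compare_survival <- function(scores, clinical, cutoff = NULL,
                             endpoint = c("os", "pfs"), groups = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(groups)) {
    if (is.null(cutoff)) stop("supply either a cutoff or explicit groups")
    s <- as_score_vector(scores)
    groups <- stats::setNames(ifelse(s <= cutoff, "low", "high"), names(s))
  } else {
    if (is.numeric(groups)) groups <- ifelse(groups > 0, "high", "low")
    groups <- stats::setNames(as.character(groups), names(groups))
  }
  if (!is.null(names(groups))) {
    common <- intersect(names(groups), clinical$sample_id)
    if (length(common) == 0L) stop("no samples shared with the clinical table")
    groups <- groups[common]
    cl <- clinical[match(common, clinical$sample_id), ]
  } else {
    if (length(groups) != nrow(clinical)) stop("unnamed groups must match clinical rows")
    cl <- clinical
  }
  time <- if (endpoint == "os") cl$os_time else cl$pfs_time
  event <- if (endpoint == "os") cl$os_event else cl$pfs_event
  ok <- !is.na(time) & !is.na(event)
  time <- time[ok]; event <- event[ok]; groups <- groups[ok]
  if (!all(groups %in% c("low", "high"))) stop("groups must be 'low'/'high'")
  if (min(table(factor(groups, c("low", "high")))) == 0L) stop("both groups must be non-empty")
  g <- as.integer(groups == "high")
  lr <- logrank_test(time, event, g)
  cox <- survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow")
  b <- unname(cox$coefficients); se <- sqrt(unname(cox$var[1L, 1L]))
  km <- lapply(c(low = "low", high = "high"), function(lv) {
    km_curve(time[groups == lv], event[groups == lv])
  })
  med <- vapply(km, function(cv) {
    hit <- which(cv$survival <= 0.5)
    if (length(hit) == 0L) NA_real_ else cv$time[hit[1L]]
  }, numeric(1))
  structure(list(km = km, logrank_p = lr$p_value, chi_square = lr$chi_square,
                 hazard_ratio = exp(b),
                 hr_ci = c(lower = exp(b - 1.96 * se), upper = exp(b + 1.96 * se)),
                 log_hr = b, log_hr_se = se,
                 median_survival = med,
                 n = c(low = sum(groups == "low"), high = sum(groups == "high"))),
            class = "irgpi_survcomp")
}

#' @export
print.irgpi_survcomp <- function(x, ...) {
  cat(sprintf("low n=%d, high n=%d; log-rank p = %.3g\n", x$n[["low"]], x$n[["high"]],
              x$logrank_p))
  cat(sprintf("HR (high vs low) = %.2f (95%% CI %.2f-%.2f)\n",
              x$hazard_ratio, x$hr_ci[["lower"]], x$hr_ci[["upper"]]))
  invisible(x)
}

#' Survival-driven cutpoint scan
#'
#' Exhaustive scan over the distinct score values: each candidate cutoff
#' splits samples into low (score at or below the cutoff) and high groups,
#' and the cutoff minimising the log-rank p-value is returned, subject to
#' both groups holding at least `min_group_fraction` of the samples. The
#' minimal p-value is optimism-biased (no multiple-testing or
#' minimum-p correction is applied); a message notes this.
#'
#' @param scores Score table or named numeric vector.
#' @param clinical Clinical data frame.
#' @param min_group_fraction Minimum fraction of samples per group.
#' @param endpoint `"os"` (default) or `"pfs"`.
#' @return A list: `cutoff`, `logrank_p`, `scan` (data frame with one row
#'   per admissible cutoff: `cutoff`, `n_low`, `n_high`, `chi_square`,
#'   `p_value`).
#' @export
os_driven_cutpoint <- function(scores, clinical, min_group_fraction = 0.10,
                               endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  s <- as_score_vector(scores)
  if (!is.null(names(s))) {
    common <- intersect(names(s), clinical$sample_id)
    s <- s[common]
    cl <- clinical[match(common, clinical$sample_id), ]
  } else {
    if (length(s) != nrow(clinical)) stop("unnamed scores must match clinical rows")
    cl <- clinical
  }
  time <- if (endpoint == "os") cl$os_time else cl$pfs_time
  event <- if (endpoint == "os") cl$os_event else cl$pfs_event
  ok <- !is.na(time) & !is.na(event)
  s <- s[ok]; time <- time[ok]; event <- event[ok]
  n <- length(s)
  if (n < 20L) stop("need at least 20 subjects with the chosen endpoint")
  cand <- sort(unique(s))
  rows <- lapply(cand, function(cut) {
    n_low <- sum(s <= cut); n_high <- n - n_low
    if (n_low < min_group_fraction * n || n_high < min_group_fraction * n) return(NULL)
    lr <- tryCatch(logrank_test(time, event, as.integer(s > cut)),
                   error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    data.frame(cutoff = cut, n_low = n_low, n_high = n_high,
               chi_square = lr$chi_square, p_value = lr$p_value)
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0L) stop("no admissible cutoff under the group-size constraint")
  best <- which.min(scan$p_value)  # ties: lowest cutoff (scan is score-ordered)
  message("cutpoint chosen by minimal log-rank p; this p-value is optimism-biased")
  list(cutoff = scan$cutoff[best], logrank_p = scan$p_value[best], scan = scan)
}

#' Fixed-effect inverse-variance meta-analysis of log hazard ratios
#'
#' Pooled estimate \eqn{\hat\mu = \sum w_i x_i / \sum w_i} with
#' \eqn{w_i = 1/se_i^2}, \eqn{SE = 1/\sqrt{\sum w_i}}, 95% CI
#' \eqn{\hat\mu \pm 1.96\,SE} (exponentiated on the HR scale), Cochran's
#' \eqn{Q = \sum w_i (x_i - \hat\mu)^2}, \eqn{I^2 = \max(0, (Q - df)/Q)
#' \cdot 100} and a heterogeneity p-value from chi-square with k-1 df.
#'
#' @param log_hr Per-study log hazard ratios.
#' @param se Per-study standard errors (> 0).
#' @param labels Optional study labels.
#' @return A list of class `irgpi_meta`: `studies` (data frame),
#'   `pooled_log_hr`, `pooled_se`, `pooled_hr`, `hr_ci`, `q_statistic`,
#'   `i_squared`, `heterogeneity_p`.
#' @export
meta_fixed_effect <- function(log_hr, se, labels = NULL) {
  k <- length(log_hr)
  if (k < 1L || length(se) != k) stop("log_hr and se must be non-empty and equal length")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be finite and > 0")
  w <- 1 / se^2
  pooled <- sum(w * log_hr) / sum(w)
  pse <- 1 / sqrt(sum(w))
  q <- sum(w * (log_hr - pooled)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  het_p <- if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  structure(list(
    studies = data.frame(label = if (is.null(labels)) paste0("study", seq_len(k)) else labels,
                         log_hr = log_hr, se = se, weight = w / sum(w)),
    pooled_log_hr = pooled, pooled_se = pse,
    pooled_hr = exp(pooled),
    hr_ci = c(lower = exp(pooled - 1.96 * pse), upper = exp(pooled + 1.96 * pse)),
    q_statistic = q, i_squared = i2, heterogeneity_p = het_p),
    class = "irgpi_meta")
}

#' @export
print.irgpi_meta <- function(x, ...) {
  cat(sprintf("fixed-effect pooled HR = %.2f (95%% CI %.2f-%.2f) over %d studies\n",
              x$pooled_hr, x$hr_ci[["lower"]], x$hr_ci[["upper"]], nrow(x$studies)))
  cat(sprintf("Q = %.3f, I^2 = %.1f%%, heterogeneity p = %.3g\n",
              x$q_statistic, x$i_squared, x$heterogeneity_p))
  invisible(x)
}
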