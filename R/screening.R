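# Internal workhorse: log-rank O-E, V, chi-square for many 0/1 group
# assignments over one set of (time, event) data. G is a groups x samples
# 0/1 matrix. Returns per-row statistics; rows where the test is undefined
# (one-sided split or zero variance) get chi_square = NA.
logrank_core <- function(time, event, G) {
  stopifnot(length(time) == ncol(G), length(event) == ncol(G))
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    return(data.frame(chi_square = rep(NA_real_, nrow(G)),
                      o_minus_e = NA_real_, variance = NA_real_))
  }
  A <- outer(time, et, `>=`) * 1        # at risk at each event time
  Ev <- outer(time, et, `==`) * event   # events at each event time
  n_k <- colSums(A)
  d_k <- colSums(Ev)
  N1 <- G %*% A                          # group-1 at risk
  D1 <- G %*% Ev                         # group-1 events
  frac <- sweep(N1, 2L, n_k, `/`)
  OmE <- rowSums(D1 - sweep(frac, 2L, d_k, `*`))
  vterm <- d_k * (n_k - d_k) / pmax(n_k - 1, 1)
  vterm[n_k <= 1] <- 0
  V <- rowSums(sweep(frac * (1 - frac), 2L, vterm, `*`))
  chi <- ifelse(V > 0, OmE^2 / V, NA_real_)
  data.frame(chi_square = chi, o_minus_e = OmE, variance = V)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test. At each distinct event time with
#' \eqn{n} subjects at risk, \eqn{n_1} of them in group 1, and \eqn{d}
#' events of which \eqn{d_1} in group 1, the observed-minus-expected
#' contribution is \eqn{d_1 - d\,n_1/n} and the hypergeometric variance is
#' \eqn{d\,(n_1/n)(1-n_1/n)(n-d)/(n-1)}. The statistic
#' \eqn{(O-E)^2/V} is referred to a chi-square distribution with 1 df.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator, 1 = event, 0 = censored.
#' @param group Group membership, coded 0/1 (or a two-level factor).
#' @return A list with `chi_square`, `p_value` and `group_sizes` (n0, n1).
#' @export
logrank_test <- function(time, event, group) {
  if (is.factor(group) || is.character(group)) group <- as.integer(factor(group)) - 1L
  if (!all(group %in% c(0, 1))) stop("group must be binary (0/1 or two levels)")
  if (length(unique(group)) < 2L) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("log-rank test needs at least one event")
  res <- logrank_core(time, event, matrix(as.numeric(group), nrow = 1L))
  if (is.na(res$chi_square)) stop("log-rank variance is zero; groups not comparable at any event time")
  list(chi_square = res$chi_square,
       p_value = stats::pchisq(res$chi_square, df = 1L, lower.tail = FALSE),
       group_sizes = c(n0 = sum(group == 0), n1 = sum(group == 1)))
}

#' Screen gene pairs for survival association
#'
#' One univariate survival test per pair, the two groups being the samples
#' with pair indicator 0 and 1. Pairs whose indicator is constant in the
#' analysed samples (possible after subsetting), or whose test variance is
#' zero, are assigned p = 1 and flagged rather than dropped, keeping the
#' result aligned with the pair list. Benjamini-Hochberg FDR values are
#' appended.
#'
#' @param indicators Pair x sample 0/1 matrix from
#'   [compute_pair_indicators()] (or [merge_indicator_matrices()]).
#' @param clinical Clinical data frame from [read_clinical()].
#' @param endpoint `"os"` (default) or `"pfs"`.
#' @param method `"logrank"` (default) or `"cox"`, a univariate Cox Wald
#'   test — asymptotically equivalent for a binary covariate.
#' @return A data frame with one row per pair: `pair_label`, `chi_square`,
#'   `p_value`, `fdr`, `n0`, `n1`, `flagged`.
#' @export
screen_pairs <- function(indicators, clinical, endpoint = c("os", "pfs"),
                         method = c("logrank", "cox")) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  common <- intersect(colnames(indicators), clinical$sample_id)
  if (length(common) == 0L) stop("no samples shared between indicators and clinical table")
  ind <- indicators[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  time <- if (endpoint == "os") cl$os_time else cl$pfs_time
  event <- if (endpoint == "os") cl$os_event else cl$pfs_event
  ok <- !is.na(time) & !is.na(event)
  if (!all(ok)) {
    ind <- ind[, ok, drop = FALSE]
    time <- time[ok]; event <- event[ok]
  }
  if (length(time) == 0L) stop("endpoint '", endpoint, "' unavailable for the shared samples")
  n1 <- as.integer(rowSums(ind))
  n0 <- ncol(ind) - n1
  if (method == "logrank") {
    res <- logrank_core(time, event, ind)
    chi <- res$chi_square
  } else {
    chi <- vapply(seq_len(nrow(ind)), function(i) {
      x <- ind[i, ]
      if (length(unique(x)) < 2L) return(NA_real_)
      fit <- tryCatch(
        survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow"),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(fit) || is.na(fit$coefficients)) return(NA_real_)
      unname(fit$coefficients^2 * fit$var[1L, 1L]^-1)
    }, numeric(1))
  }
  flagged <- is.na(chi) | n0 == 0L | n1 == 0L
  chi[flagged] <- 0
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  p[flagged] <- 1
  if (any(flagged)) message(sum(flagged), " pair(s) untestable (constant or zero variance); p set to 1")
  data.frame(pair_label = rownames(ind), chi_square = chi, p_value = p,
             fdr = bh_fdr(p), n0 = n0, n1 = n1, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}, clipped at
#' 1, mapped back to input order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select candidate pairs by FDR
#'
#' Pairs with FDR strictly below the threshold, sorted by FDR then pair
#' label. An empty selection is allowed (a message is emitted).
#'
#' @param screening Data frame from [screen_pairs()].
#' @param fdr_threshold Strict upper bound on FDR; default 0.001.
#' @return The selected rows of `screening`, re-sorted.
#' @export
select_candidates <- function(screening, fdr_threshold = 0.001) {
  sel <- screening[screening$fdr < fdr_threshold, , drop = FALSE]
  sel <- sel[order(sel$fdr, sel$pair_label), , drop = FALSE]
  if (nrow(sel) == 0L) message("no pairs pass FDR < ", fdr_threshold)
  rownames(sel) <- NULL
  sel
}
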