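#' Single-sample gene-set enrichment scores
#'
#' Barbie-style ssGSEA: within each sample, genes are ranked by expression
#' (descending walk order; average ranks for ties, so the top gene has rank
#' value N). Walking down the ranked list, the in-set cumulative
#' distribution weights each in-set gene by its rank value to the power
#' `alpha`, the out-of-set cumulative distribution is uniform, and the
#' enrichment score is the sum of the running differences (the integrated
#' deviation between the two walks). With `alpha = 0` the score is a pure
#' rank statistic, exactly invariant to strictly increasing per-sample
#' transformations of expression.
#'
#' @param expr Genes x samples numeric matrix.
#' @param sets Named list of gene-symbol vectors (see [read_gmt()]). Sets
#'   sharing fewer than 2 genes with `expr` are skipped with a warning; a
#'   set covering every gene is an error.
#' @param alpha Rank-weight exponent; default 0.25.
#' @param normalize If TRUE, divide all scores by the global (max - min)
#'   across the score matrix. Default FALSE.
#' @return Numeric matrix, sets x samples.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  n <- nrow(expr)
  usable <- vapply(sets, function(g) sum(g %in% rownames(expr)), integer(1))
  if (any(usable >= n)) {
    stop("gene set(s) covering every expressed gene: ",
         paste(names(sets)[usable >= n], collapse = ", "))
  }
  skip <- usable < 2L
  if (any(skip)) {
    warning("skipping ", sum(skip), " set(s) sharing < 2 genes with the expression matrix: ",
            paste(names(sets)[skip], collapse = ", "))
    sets <- sets[!skip]
  }
  if (length(sets) == 0L) stop("no usable gene sets")
  member <- vapply(sets, function(g) rownames(expr) %in% g, logical(n))  # n x sets
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    ord <- order(x, decreasing = TRUE)
    r <- rank(x)  # average ties; top gene ~ n
    w_all <- r[ord]^alpha
    for (k in seq_along(sets)) {
      inset <- member[ord, k]
      w <- w_all * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (n - sum(inset))
      out[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) out <- out / (max(out) - min(out))
  out
}

#' Compare per-sample features between two groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) of each feature between the high and low groups, with
#' Benjamini-Hochberg adjustment across features. A feature that is
#' constant over all samples gets p = 1 and is flagged.
#'
#' @param features Numeric matrix (features x samples) or a single numeric
#'   vector.
#' @param groups Group assignment per sample: values `"high"`/`"low"`, a
#'   logical (TRUE = high), or 0/1 (1 = high). Both groups need >= 3
#'   samples.
#' @return Data frame with one row per feature: `feature`, `median_high`,
#'   `median_low`, `statistic` (Mann-Whitney U of the high group), `p_value`,
#'   `fdr`, `flagged`.
#' @export
compare_feature_by_group <- function(features, groups) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list("feature", names(features)))
  }
  if (is.logical(groups)) groups <- ifelse(groups, "high", "low")
  if (is.numeric(groups)) groups <- ifelse(groups > 0, "high", "low")
  groups <- as.character(groups)
  if (!all(groups %in% c("high", "low"))) stop("groups must be 'high'/'low' (or logical/0-1)")
  hi <- groups == "high"
  if (sum(hi) < 3L || sum(!hi) < 3L) stop("both groups need at least 3 samples")
  res <- lapply(seq_len(nrow(features)), function(i) {
    x <- features[i, hi]; y <- features[i, !hi]
    if (length(unique(c(x, y))) < 2L) {
      return(data.frame(statistic = NA_real_, p_value = 1, flagged = TRUE))
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    data.frame(statistic = unname(wt$statistic), p_value = wt$p.value, flagged = FALSE)
  })
  res <- do.call(rbind, res)
  data.frame(feature = rownames(features),
             median_high = apply(features[, hi, drop = FALSE], 1L, stats::median),
             median_low = apply(features[, !hi, drop = FALSE], 1L, stats::median),
             statistic = res$statistic, p_value = res$p_value,
             fdr = bh_fdr(res$p_value), flagged = res$flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}
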