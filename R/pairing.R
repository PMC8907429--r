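#' Enumerate candidate gene pairs
#'
#' A gene pair `A|B` scores 1 in a sample when A's expression strictly
#' exceeds B's. In canonical mode one pair is produced per unordered gene
#' couple (lexicographically smaller symbol first, `n*(n-1)/2` pairs);
#' `B|A` carries the same information as `A|B` with the indicator flipped,
#' so canonical is the non-redundant default. `"both"` enumerates all
#' `n*(n-1)` ordered pairs.
#'
#' @param genes Character vector of at least two unique gene symbols.
#' @param orientation `"canonical"` (default) or `"both"`.
#' @return A data frame with columns `gene_a`, `gene_b`, `label`
#'   (`"A|B"`).
#' @export
enumerate_candidate_pairs <- function(genes, orientation = c("canonical", "both")) {
  orientation <- match.arg(orientation)
  genes <- unique(trimws(genes))
  if (length(genes) < 2L) stop("need at least 2 genes to form pairs")
  if (orientation == "canonical") {
    genes <- sort(genes)
    idx <- utils::combn(length(genes), 2L)
    a <- genes[idx[1L, ]]
    b <- genes[idx[2L, ]]
  } else {
    grid <- expand.grid(b = genes, a = genes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    a <- grid$a
    b <- grid$b
  }
  data.frame(gene_a = a, gene_b = b, label = paste0(a, "|", b),
             stringsAsFactors = FALSE)
}

#' Binary pair-indicator matrix
#'
#' For each pair and sample, the indicator is 1 iff the expression of
#' `gene_a` is strictly greater than that of `gene_b` within that sample;
#' ties and every other case score 0. Because only within-sample order
#' matters, the indicator matrix is exactly invariant to any strictly
#' increasing per-sample transformation of expression — the property that
#' lets matrices from different platforms be concatenated without
#' normalisation.
#'
#' @param expr Genes x samples numeric matrix.
#' @param pairs Pair data frame from [enumerate_candidate_pairs()] (or any
#'   data frame with `gene_a`, `gene_b` columns; a `label` column is added
#'   if absent).
#' @return Integer 0/1 matrix, pairs (rownames = labels) x samples, with the
#'   pair table attached as attribute `"pairs"` and the cohort label carried
#'   over as attribute `"cohort"`.
#' @export
compute_pair_indicators <- function(expr, pairs) {
  if (is.null(pairs$label)) pairs$label <- paste0(pairs$gene_a, "|", pairs$gene_b)
  need <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(need, rownames(expr))
  if (length(missing) > 0L) {
    stop("pair gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  ind <- (expr[pairs$gene_a, , drop = FALSE] >
          expr[pairs$gene_b, , drop = FALSE]) * 1L
  rownames(ind) <- pairs$label
  storage.mode(ind) <- "integer"
  attr(ind, "pairs") <- pairs
  attr(ind, "cohort") <- attr(expr, "cohort")
  ind
}

#' Remove near-constant pairs across cohorts
#'
#' A pair is dropped when, in at least one cohort, its indicator takes the
#' value 0 or the value 1 in strictly more than `threshold` of that cohort's
#' samples ("over 80%" by default); such pairs cannot separate survival
#' groups. All matrices must share the same pair list. The frequency check
#' runs over row blocks so the full pair x sample matrix never needs to be
#' examined at once; the result is independent of `block_size`.
#'
#' @param matrices A list of indicator matrices from
#'   [compute_pair_indicators()] sharing one pair list, one per cohort
#'   (a single matrix is also accepted).
#' @param threshold Constancy threshold, a fraction in (0.5, 1]; default 0.8.
#' @param block_size Rows per processing block.
#' @return The kept pairs as a data frame (`gene_a`, `gene_b`, `label`).
#' @export
filter_constant_pairs <- function(matrices, threshold = 0.8, block_size = 50000L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  labels <- rownames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(rownames(m), labels)) stop("indicator matrices have mismatched pair lists")
  }
  keep <- rep(TRUE, length(labels))
  starts <- seq(1L, length(labels), by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, length(labels))
    for (m in matrices) {
      freq1 <- rowMeans(m[rows, , drop = FALSE])
      keep[rows] <- keep[rows] & (freq1 <= threshold) & (1 - freq1 <= threshold)
    }
  }
  pairs <- attr(matrices[[1L]], "pairs")
  if (is.null(pairs)) {
    sp <- strsplit(labels, "|", fixed = TRUE)
    pairs <- data.frame(gene_a = vapply(sp, `[`, "", 1L),
                        gene_b = vapply(sp, `[`, "", 2L),
                        label = labels, stringsAsFactors = FALSE)
  }
  pairs[keep, , drop = FALSE]
}

#' Concatenate cohort indicator matrices into a meta cohort
#'
#' Pair indicators are rank-based, so matrices from different platforms can
#' be joined column-wise with no renormalisation.
#'
#' @param matrices List of indicator matrices sharing one pair list.
#' @return A single indicator matrix with all samples.
#' @export
merge_indicator_matrices <- function(matrices) {
  labels <- rownames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(rownames(m), labels)) stop("indicator matrices have mismatched pair lists")
  }
  out <- do.call(cbind, matrices)
  if (anyDuplicated(colnames(out))) stop("duplicated sample ids across cohorts")
  attr(out, "pairs") <- attr(matrices[[1L]], "pairs")
  attr(out, "cohort") <- "meta"
  out
}
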