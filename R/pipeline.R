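# Run manifest: enough metadata to reproduce a pipeline invocation.
write_manifest <- function(out_dir, command, config = list(), inputs = character(0)) {
  man <- list(command = command,
              package = "irgpi",
              version = as.character(utils::packageVersion("irgpi")),
              config = config,
              input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full signature-discovery chain on one or more cohorts
#'
#' Orchestrates the discovery pipeline: shared-gene intersection
#' (optionally restricted to a user-supplied immune-gene list), candidate
#' pair enumeration, per-cohort indicator matrices, constant-pair filtering
#' (a pair near-constant in any cohort is removed), concatenation into a
#' meta cohort, per-pair log-rank screening with Benjamini-Hochberg FDR,
#' candidate selection, and the penalised-then-refit Cox signature fit.
#'
#' @param cohorts List of cohorts, each a list with `$expression` (genes x
#'   samples matrix), `$clinical` (from [read_clinical()] or the synthetic
#'   generator) and `$name`.
#' @param fit_cfg Fitting options from [fit_config()] (seeded).
#' @param immune_genes Optional gene list to restrict the universe to.
#' @param filter_threshold Constancy threshold for [filter_constant_pairs()].
#' @param fdr_threshold Strict FDR bound for candidate selection.
#' @param orientation Pair orientation, `"canonical"` or `"both"`.
#' @param endpoint Screening/fitting endpoint, `"os"` or `"pfs"`.
#' @param out_dir Optional directory; when given, the screening table,
#'   kept-pair list, signature TSV and a run manifest are written there.
#' @return A list: `signature`, `screening`, `candidates`, `kept_pairs`,
#'   `indicators` (meta-cohort matrix), `clinical` (merged), `genes`.
#' @export
run_discovery <- function(cohorts, fit_cfg, immune_genes = NULL,
                          filter_threshold = 0.8, fdr_threshold = 0.001,
                          orientation = "canonical", endpoint = "os",
                          out_dir = NULL) {
  genes <- intersect_genes(cohorts, restrict_to = immune_genes)
  pairs <- enumerate_candidate_pairs(genes, orientation = orientation)
  per_cohort <- lapply(cohorts, function(co) compute_pair_indicators(co$expression, pairs))
  kept <- filter_constant_pairs(per_cohort, threshold = filter_threshold)
  if (nrow(kept) == 0L) stop("every pair is near-constant in some cohort; nothing to screen")
  per_cohort <- lapply(per_cohort, function(m) {
    out <- m[kept$label, , drop = FALSE]
    attr(out, "pairs") <- kept
    out
  })
  meta <- merge_indicator_matrices(per_cohort)
  clinical <- do.call(rbind, lapply(cohorts, function(co) {
    cl <- co$clinical
    cl$cohort <- co$name
    cl
  }))
  rownames(clinical) <- NULL
  screening <- screen_pairs(meta, clinical, endpoint = endpoint)
  candidates <- select_candidates(screening, fdr_threshold = fdr_threshold)
  if (nrow(candidates) == 0L) {
    stop(structure(class = c("irgpi_empty_candidates", "error", "condition"),
                   list(message = paste0("no pairs pass FDR < ", fdr_threshold,
                                         "; signature not fitted"),
                        call = sys.call())))
  }
  cand_ind <- meta[candidates$pair_label, , drop = FALSE]
  attr(cand_ind, "pairs") <- kept[match(candidates$pair_label, kept$label), ]
  signature <- fit_signature(cand_ind, clinical, fit_cfg, endpoint = endpoint)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(screening, file.path(out_dir, "screening.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(kept$label, file.path(out_dir, "kept_pairs.txt"))
    write_signature(signature, file.path(out_dir, "signature.tsv"))
    write_manifest(out_dir, "build",
                   config = list(filter_threshold = filter_threshold,
                                 fdr_threshold = fdr_threshold,
                                 orientation = orientation, endpoint = endpoint,
                                 fit = fit_cfg))
  }
  list(signature = signature, screening = screening, candidates = candidates,
       kept_pairs = kept, indicators = meta, clinical = clinical, genes = genes)
}

#' Score cohorts against a signature and evaluate classification/survival
#'
#' Computes per-sample scores from expression, then — depending on the
#' cutoff mode — a ROC/Youden analysis (`"youden"`), a fixed threshold
#' (`"fixed"`), or a survival-driven cutpoint scan (`"os_scan"`, for
#' cohorts without response labels). Classification metrics are reported
#' when response labels exist, the low/high survival comparison always.
#' With a per-sample cohort assignment, per-cohort hazard ratios are pooled
#' by fixed-effect meta-analysis.
#'
#' @param expression Genes x samples matrix (a single cohort or a merged
#'   matrix).
#' @param clinical Clinical data frame; an optional `cohort` column drives
#'   the meta-analysis.
#' @param model An `irgpi_signature` (e.g. [load_bundled_signature()] or a
#'   fitted one).
#' @param cutoff_mode `"youden"`, `"fixed"` or `"os_scan"`.
#' @param cutoff Threshold value, required for `"fixed"`.
#' @param missing_policy Passed to [score_cohort_from_expression()].
#' @param direction Classification direction; default low score = predicted
#'   responder.
#' @param out_dir Optional output directory (scores, ROC table, confusion,
#'   KM curves, meta table, manifest).
#' @return A list: `scores`, `cutoff`, `roc` (or `cutpoint`), `confusion`,
#'   `survival`, `meta` (NULL without a cohort column or with a single
#'   cohort).
#' @export
run_evaluation <- function(expression, clinical, model,
                           cutoff_mode = c("youden", "fixed", "os_scan"),
                           cutoff = NULL,
                           missing_policy = "error",
                           direction = "low_is_positive",
                           out_dir = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  scores <- score_cohort_from_expression(expression, model, missing_policy)
  s <- stats::setNames(scores$irgpi, scores$sample_id)
  cl <- clinical[clinical$sample_id %in% names(s), , drop = FALSE]
  labels <- stats::setNames(cl$responder, cl$sample_id)
  have_labels <- any(!is.na(labels))
  roc <- NULL; cutpoint <- NULL
  if (cutoff_mode == "youden") {
    if (!have_labels) stop("cutoff_mode 'youden' needs response labels")
    roc <- roc_and_youden(s[names(labels)], labels, direction = direction)
    cutoff <- roc$youden_cutoff
  } else if (cutoff_mode == "os_scan") {
    cutpoint <- os_driven_cutpoint(s, cl)
    cutoff <- cutpoint$cutoff
  } else if (is.null(cutoff) || !is.finite(cutoff)) {
    stop("cutoff_mode 'fixed' needs a finite cutoff value")
  }
  confusion <- if (have_labels) {
    classify_and_confuse(s[names(labels)], cutoff, labels, direction = direction)
  }
  surv <- compare_survival(s, cl, cutoff = cutoff)
  meta <- NULL
  if ("cohort" %in% names(cl) && length(unique(cl$cohort)) > 1L) {
    per <- lapply(split(cl, cl$cohort), function(sub) {
      tryCatch(compare_survival(s[sub$sample_id], sub, cutoff = cutoff),
               error = function(e) NULL)
    })
    per <- Filter(Negate(is.null), per)
    if (length(per) >= 2L) {
      meta <- meta_fixed_effect(vapply(per, `[[`, 0, "log_hr"),
                                vapply(per, `[[`, 0, "log_hr_se"),
                                labels = names(per))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(roc)) {
      utils::write.table(
        data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
                   specificity = roc$specificity),
        file.path(out_dir, "roc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(confusion)) {
      utils::write.table(
        data.frame(tp = confusion$tp, fn = confusion$fn, tn = confusion$tn,
                   fp = confusion$fp, sensitivity = confusion$sensitivity,
                   specificity = confusion$specificity, accuracy = confusion$accuracy),
        file.path(out_dir, "confusion.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (g in names(surv$km)) {
      utils::write.table(surv$km[[g]], file.path(out_dir, paste0("km_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(meta)) {
      utils::write.table(meta$studies, file.path(out_dir, "meta_studies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, "evaluate",
                   config = list(cutoff_mode = cutoff_mode, cutoff = cutoff,
                                 direction = direction, model = model$name))
  }
  list(scores = scores, cutoff = cutoff, roc = roc, cutpoint = cutpoint,
       confusion = confusion, survival = surv, meta = meta)
}
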