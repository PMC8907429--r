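#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file with gene symbols in the first column and one
#' column per sample. Units are arbitrary: every downstream operation uses
#' only the within-sample rank order of expression values.
#'
#' Duplicate gene symbols are resolved by keeping the row with the highest
#' mean expression (a message reports how many rows were dropped). Gene
#' symbols are matched case-sensitively after trimming whitespace; no alias
#' resolution is attempted.
#'
#' @param path Path to a tab- or comma-delimited text file. The delimiter is
#'   detected from the header line.
#' @param missing_policy What to do with missing cells: `"error"` (default)
#'   aborts; `"drop_gene"` removes every gene row containing a missing value.
#' @param cohort_label Optional cohort name stored as the `"cohort"`
#'   attribute; defaults to the file name without extension.
#' @return A numeric matrix (genes x samples) with unique rownames and
#'   colnames, all values finite and non-negative, and a `"cohort"` attribute.
#' @export
read_expression_matrix <- function(path, missing_policy = c("error", "drop_gene"),
                                   cohort_label = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty expression file: ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""), comment.char = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus >=1 sample column")
  genes <- trimws(as.character(raw[[1L]]))
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1L]], genes[bad[1L]], names(vals)[j]))
      }
      vals[[j]] <- as.numeric(col)
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  if (anyNA(mat)) {
    if (missing_policy == "error") {
      idx <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (missing_policy = \"error\")",
                   genes[idx[1L]], colnames(mat)[idx[2L]]))
    }
    keep <- rowSums(is.na(mat)) == 0L
    message(sum(!keep), " gene(s) dropped for missing values")
    mat <- mat[keep, , drop = FALSE]
  }
  if (any(mat < 0)) stop("negative expression values are not allowed")
  if (anyDuplicated(rownames(mat))) {
    means <- rowMeans(mat)
    ord <- order(-means)  # highest-mean row wins
    mat <- mat[ord, , drop = FALSE]
    dup <- duplicated(rownames(mat))
    message(sum(dup), " duplicated gene row(s) resolved by highest mean expression")
    mat <- mat[!dup, , drop = FALSE]
  }
  if (anyDuplicated(colnames(mat))) stop("duplicated sample identifiers in header")
  if (nrow(mat) == 0L) stop("no gene rows left after applying the missing-value policy")
  attr(mat, "cohort") <- if (is.null(cohort_label)) {
    sub("\\.[^.]*$", "", basename(path))
  } else cohort_label
  mat
}

#' Write an expression matrix as TSV
#'
#' Values are written with full precision (`format(..., digits = 17)`) so a
#' write/read round trip reproduces the matrix bit-identically.
#'
#' @param mat Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a delimited text file with columns `sample_id`, `os_time`
#' (months), `os_event` (0 censored / 1 death) and optionally `pfs_time`,
#' `pfs_event` and `response` (RECIST: CR, PR, SD, PD). Records with
#' non-positive overall-survival time are rejected with a message; an
#' unrecognised response code is an error.
#'
#' @param path Path to a TSV/CSV clinical table.
#' @return A data frame with columns `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`, `response` and a logical `responder` column
#'   (`TRUE` for CR/PR, `NA` when response is absent).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  required <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("pfs_time", "pfs_event", "response")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  df$response <- toupper(trimws(as.character(df$response)))
  df$response[df$response == ""] <- NA_character_
  bad_resp <- setdiff(unique(df$response[!is.na(df$response)]), c("CR", "PR", "SD", "PD"))
  if (length(bad_resp) > 0L) {
    stop("unknown response code(s): ", paste(bad_resp, collapse = ", "),
         " (expected CR, PR, SD, PD)")
  }
  if (!all(df$os_event %in% c(0L, 1L))) stop("os_event must be 0 or 1")
  drop <- is.na(df$os_time) | df$os_time <= 0
  if (any(drop)) {
    message(sum(drop), " clinical record(s) rejected for non-positive or missing os_time")
    df <- df[!drop, , drop = FALSE]
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  df$responder <- ifelse(is.na(df$response), NA, df$response %in% c("CR", "PR"))
  rownames(df) <- NULL
  df[, c("sample_id", "os_time", "os_event", "pfs_time", "pfs_event",
         "response", "responder")]
}

#' Write a clinical table as TSV
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  cols <- intersect(c("sample_id", "os_time", "os_event", "pfs_time",
                      "pfs_event", "response"), names(clinical))
  utils::write.table(clinical[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols. Duplicate genes within a set are
#' removed; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) < 3L) stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nms[i] <- fields[1L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("GMT line ", i, " (set '", fields[1L], "') has no genes")
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) stop("duplicated gene-set names in GMT file")
  stats::setNames(sets, nms)
}

#' Genes shared by every cohort
#'
#' Returns the sorted intersection of gene identifiers across a list of
#' expression matrices, optionally restricted to a supplied gene list (for
#' example an ImmPort-style immune-gene catalogue, which is a user input —
#' no gene catalogue is packaged).
#'
#' @param cohorts A list of expression matrices (or of lists with an
#'   `$expression` element).
#' @param restrict_to Optional character vector of gene symbols to intersect
#'   with first.
#' @return Sorted character vector of shared gene symbols.
#' @export
intersect_genes <- function(cohorts, restrict_to = NULL) {
  if (length(cohorts) < 1L) stop("need at least one cohort")
  gene_lists <- lapply(cohorts, function(x) {
    m <- if (is.list(x) && !is.null(x$expression)) x$expression else x
    rownames(m)
  })
  shared <- Reduce(intersect, gene_lists)
  if (!is.null(restrict_to)) shared <- intersect(shared, trimws(restrict_to))
  if (length(shared) == 0L) stop("no genes shared across the supplied cohorts")
  sort(shared)
}
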