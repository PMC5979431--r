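#' Read a genes-by-samples RPKM matrix
#'
#' Expects a rectangular text table: header row of sample identifiers, first
#' column gene identifiers, every other cell a nonnegative RPKM value.
#' Parsing is strict: a missing, non-numeric or negative cell is an error
#' naming the offending gene and sample, and duplicate gene identifiers are
#' rejected — the downstream statistics assume complete replicate matrices,
#' so nothing is imputed.
#'
#' @param path Path to the file.
#' @param dialect "tsv" (default) or "csv".
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @seealso [write_expression_matrix()] for the inverse operation.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression matrix needs a gene column and >=1 sample column")
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
                dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) | !nzchar(trimws(col)))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], genes[bad[1L]], sample_ids[j]))
    }
    neg <- which(val < 0)
    if (length(neg) > 0L) {
      stop(sprintf("negative value %s at gene '%s', sample '%s'",
                   col[neg[1L]], genes[neg[1L]], sample_ids[j]))
    }
    mat[, j] <- val
  }
  mat
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with "%.17g" so that a write/read round trip restores
#' every double bit-for-bit; header column for gene ids is named "gene".
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  header <- paste(c("gene", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A TSV with columns `sample_id`, `tissue`, `cohort`, `replicate`. Cohort
#' labels are translated through `cohort_map` (by default "1W" -> young,
#' "4W" -> aged, "4W-IF" -> aged_treated; canonical names pass through).
#' Duplicate sample ids, unknown cohort or tissue labels, and duplicate
#' replicate indices within a (tissue, cohort) group are errors.
#'
#' @param path Path to the TSV.
#' @param cohort_map Named character vector mapping file labels to canonical
#'   cohort levels.
#' @param tissues Accepted tissue labels.
#' @return A data.frame with columns sample_id (character), tissue (factor),
#'   cohort (factor with levels [cohort_levels()]), replicate (integer).
#' @export
read_sample_sheet <- function(path, cohort_map = default_cohort_map(),
                              tissues = tissue_levels()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "cohort", "replicate")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0L) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  }
  unknown_cohort <- setdiff(unique(df$cohort), names(cohort_map))
  if (length(unknown_cohort) > 0L) {
    stop("unknown cohort label(s): ", paste(unknown_cohort, collapse = ", "),
         " (extend cohort_map to accept them)")
  }
  unknown_tissue <- setdiff(unique(df$tissue), tissues)
  if (length(unknown_tissue) > 0L) {
    stop("unknown tissue label(s): ", paste(unknown_tissue, collapse = ", "))
  }
  df$cohort <- factor(unname(cohort_map[df$cohort]), levels = cohort_levels())
  df$tissue <- factor(df$tissue, levels = tissues)
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1L)) {
    stop("replicate indices must be positive integers")
  }
  df$replicate <- rep_num
  key <- interaction(df$tissue, df$cohort, drop = TRUE)
  for (g in levels(key)) {
    reps <- df$replicate[key == g]
    if (anyDuplicated(reps)) {
      stop("duplicate replicate index within group ", g)
    }
  }
  df[, required]
}

#' Build a sample sheet in memory
#'
#' Convenience constructor applying the same validation as
#' [read_sample_sheet()] without touching the file system.
#'
#' @param sample_id,tissue,cohort,replicate Equal-length vectors.
#' @return A validated sample-sheet data.frame.
#' @export
sample_sheet <- function(sample_id, tissue, cohort, replicate) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(
    data.frame(sample_id = sample_id, tissue = tissue, cohort = cohort,
               replicate = replicate, stringsAsFactors = FALSE),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_sample_sheet(tmp)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are counted once; a set
#' with no members is skipped with a warning; a line with fewer than two
#' fields is an error reporting the line number.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> unique member ids).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop(sprintf("malformed GMT line %d: expected name<TAB>description<TAB>members", i))
    }
    members <- unique(fields[-c(1L, 2L)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      warning(sprintf("GMT line %d ('%s'): empty set skipped", i, fields[1L]))
      next
    }
    sets[[fields[1L]]] <- members
  }
  sets
}

#' Cross-check an expression matrix against a sample sheet
#'
#' Matching is by sample id and order-insensitive. The report lists matrix
#' columns absent from the sheet and sheet samples absent from the matrix;
#' the pipeline refuses to run on a non-empty mismatch unless forced.
#'
#' @param matrix Expression matrix (samples in columns).
#' @param samples Sample-sheet data.frame.
#' @return A list with elements `missing_in_sheet`, `missing_in_matrix` and
#'   logical `ok`, of class `txdrift_validation`.
#' @export
validate_dataset <- function(matrix, samples) {
  in_matrix <- colnames(matrix)
  in_sheet <- samples$sample_id
  report <- list(
    missing_in_sheet = setdiff(in_matrix, in_sheet),
    missing_in_matrix = setdiff(in_sheet, in_matrix)
  )
  report$ok <- length(report$missing_in_sheet) == 0L &&
    length(report$missing_in_matrix) == 0L
  class(report) <- "txdrift_validation"
  report
}

#' @export
print.txdrift_validation <- function(x, ...) {
  if (x$ok) {
    cat("dataset valid: matrix columns and sample sheet agree\n")
  } else {
    if (length(x$missing_in_sheet)) {
      cat("matrix columns absent from sample sheet:",
          paste(x$missing_in_sheet, collapse = ", "), "\n")
    }
    if (length(x$missing_in_matrix)) {
      cat("sheet samples absent from matrix:",
          paste(x$missing_in_matrix, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# internal: tab-separated writer with full-precision numerics, stable order
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
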