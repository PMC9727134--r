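# plain-text readers/writers for the pipeline's table formats
#
# All intermediates are TSV/CSV so that any stage can be rerun standalone
# and outputs stay auditable with standard command-line tools.

#' Write a beta matrix as TSV
#'
#' First column `cpg_id`, then one column per sample id. Values are
#' methylation fractions in \[0,1\].
#'
#' @param betas numeric matrix, CpG ids as rownames, sample ids as colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  assert_beta_matrix(betas)
  df <- data.frame(cpg_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta matrix from TSV
#'
#' @param path file written by [write_beta_matrix()] (first column CpG id).
#' @return numeric matrix with CpG rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix file needs a CpG id column plus >=1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write / read a sample sheet
#'
#' CSV with header `sample_id,individual_id,tissue,group,age_years`.
#' @param sheet data.frame with those columns.
#' @param path file path.
#' @return `path` (write) or the sheet data.frame (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write.csv(sheet[, sheet_columns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

sheet_columns <- function() c("sample_id", "individual_id", "tissue", "group", "age_years")

validate_sample_sheet <- function(sheet) {
  missing <- setdiff(sheet_columns(), names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet", call. = FALSE)
  bad <- setdiff(unique(sheet$tissue), c("sperm", "blood"))
  if (length(bad) > 0L) {
    stop("unknown tissue label(s) in sample sheet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(sheet$age_years) | sheet$age_years <= 0)) {
    stop("age_years must be positive and finite", call. = FALSE)
  }
  invisible(sheet)
}

#' Write / read a per-sample median intensity table
#'
#' TSV with columns `sample_id` and `median_log2_intensity` (log2 scale of
#' the array's median signal, the usual sample-quality summary).
#' @param intensity data.frame with those columns.
#' @param path file path.
#' @export
write_intensity_table <- function(intensity, path) {
  stopifnot(all(c("sample_id", "median_log2_intensity") %in% names(intensity)))
  write.table(intensity, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @export
read_intensity_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "median_log2_intensity") %in% names(df)))
  df
}

# DLK1 annotation: one CpG id per line, '#' comments allowed
read_cpg_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

write_cpg_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
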