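# Mean-matching age adjustment and the germ-line age differential (GLAD).
#
# Linear clocks are accurate up to a cohort-level offset, so predicted ages
# are first shifted by the difference of cohort means (mean-matching):
#   d = mean(chronological) - mean(predicted);  adjusted_i = predicted_i + d.
# GLAD then expresses the residual age acceleration of each sample as a
# fraction of its chronological age,
#   GLAD_i = (adjusted_i - chronological_i) / chronological_i,
# a ratio chosen to avoid the heteroskedasticity of raw year differences
# (older samples have proportionally larger prediction errors). Positive
# GLAD means the tissue looks epigenetically older than chronology. The
# same formula applied to a somatic tissue is a "GLAD-equivalent" score.

#' Mean-matching adjustment of predicted ages
#'
#' Shifts all predicted ages by `d = mean(chronological) - mean(predicted)`
#' so that the adjusted ages have exactly the chronological mean. A single
#' constant shift preserves every within-cohort contrast.
#'
#' @param predicted,chronological numeric vectors of equal length `>= 2`,
#'   years.
#' @return adjusted predicted ages (years).
#' @export
mean_match_adjust <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("'predicted' and 'chronological' must have equal length", call. = FALSE)
  }
  if (length(predicted) < 2L) stop("need at least 2 samples to mean-match", call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(chronological))) {
    stop("non-finite age values", call. = FALSE)
  }
  predicted + (mean(chronological) - mean(predicted))
}

#' Germ-line age differential (GLAD)
#'
#' `form = "centered"` (default) computes
#' `(adjusted - chronological) / chronological`, which is zero for a sample
#' whose adjusted epigenetic age matches chronology. `form = "ratio"`
#' returns the literal quotient `adjusted / chronological` (centered near
#' 1); the two differ by exactly 1.
#'
#' @param adjusted mean-matched predicted ages (years).
#' @param chronological chronological ages (years, strictly positive).
#' @param form `"centered"` or `"ratio"`.
#' @return numeric GLAD vector.
#' @export
compute_glad <- function(adjusted, chronological, form = c("centered", "ratio")) {
  form <- match.arg(form)
  if (length(adjusted) != length(chronological)) {
    stop("'adjusted' and 'chronological' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(chronological)) || any(chronological <= 0)) {
    stop("chronological ages must be positive and finite", call. = FALSE)
  }
  r <- adjusted / chronological
  if (form == "centered") r - 1 else r
}

#' Build the per-sample GLAD table
#'
#' Joins clock predictions onto the sample sheet, performs mean-matching
#' within each tissue, and computes GLAD per sample. By default the
#' adjustment pools both groups within a tissue, so a genuine group
#' difference is not erased by per-group centering; `scope = "per_group"`
#' mean-matches each group separately (which forces every group's mean
#' GLAD toward zero and is only useful for diagnostics).
#'
#' @param predictions data.frame from [apply_clock()] (possibly rbind-ed
#'   across tissues): needs `sample_id` and `predicted_age_years`.
#' @param sheet sample sheet covering every predicted sample.
#' @param scope mean-matching scope, `"pooled"` (default) or `"per_group"`.
#' @param form GLAD form, see [compute_glad()].
#' @return data.frame with columns `sample_id`, `individual_id`, `tissue`,
#'   `group`, `age_years`, `predicted_age`, `adjusted_age`, `glad`.
#' @export
glad_table <- function(predictions, sheet, scope = c("pooled", "per_group"),
                       form = c("centered", "ratio")) {
  scope <- match.arg(scope)
  form <- match.arg(form)
  validate_sample_sheet(sheet)
  stopifnot(all(c("sample_id", "predicted_age_years") %in% names(predictions)))
  idx <- match(predictions$sample_id, sheet$sample_id)
  if (anyNA(idx)) {
    stop("prediction(s) for sample(s) absent from the sheet: ",
         paste(head(predictions$sample_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    sample_id = predictions$sample_id,
    individual_id = sheet$individual_id[idx],
    tissue = sheet$tissue[idx],
    group = sheet$group[idx],
    age_years = sheet$age_years[idx],
    predicted_age = predictions$predicted_age_years,
    adjusted_age = NA_real_,
    stringsAsFactors = FALSE)

  key <- if (scope == "pooled") out$tissue else paste(out$tissue, out$group)
  for (k in unique(key)) {
    i <- key == k
    out$adjusted_age[i] <- mean_match_adjust(out$predicted_age[i], out$age_years[i])
  }
  out$glad <- compute_glad(out$adjusted_age, out$age_years, form = form)
  out
}

#' Per-individual sperm-minus-blood predicted-age difference
#'
#' For each individual with exactly one sperm and one blood prediction,
#' returns the raw (unadjusted) predicted-age difference
#' `sperm - blood` in years. Individuals missing either tissue are excluded
#' with a warning listing them.
#'
#' @param predictions combined prediction table (both tissues); needs
#'   `sample_id` and `predicted_age_years`.
#' @param sheet sample sheet.
#' @return data.frame with `individual_id`, `group`,
#'   `sperm_predicted_age`, `blood_predicted_age`, `difference`.
#' @export
predicted_age_difference <- function(predictions, sheet) {
  validate_sample_sheet(sheet)
  idx <- match(predictions$sample_id, sheet$sample_id)
  if (anyNA(idx)) {
    stop("prediction(s) for sample(s) absent from the sheet", call. = FALSE)
  }
  df <- data.frame(individual_id = sheet$individual_id[idx],
                   group = sheet$group[idx],
                   tissue = sheet$tissue[idx],
                   predicted = predictions$predicted_age_years,
                   stringsAsFactors = FALSE)
  inds <- unique(df$individual_id)
  rows <- lapply(inds, function(id) {
    sub <- df[df$individual_id == id, ]
    sp <- sub$predicted[sub$tissue == "sperm"]
    bl <- sub$predicted[sub$tissue == "blood"]
    if (length(sp) != 1L || length(bl) != 1L) return(NULL)
    data.frame(individual_id = id, group = sub$group[1],
               sperm_predicted_age = sp, blood_predicted_age = bl,
               difference = sp - bl, stringsAsFactors = FALSE)
  })
  dropped <- inds[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0L) {
    warning("excluding individual(s) without both tissue predictions: ",
            paste(head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(individual_id = character(0), group = character(0),
                      sperm_predicted_age = numeric(0),
                      blood_predicted_age = numeric(0),
                      difference = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Write / read a GLAD table as TSV
#'
#' @param glad data.frame from [glad_table()].
#' @param path file path.
#' @export
write_glad_table <- function(glad, path) {
  write.table(glad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_glad_table
#' @export
read_glad_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
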