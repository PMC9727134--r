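# Sample-level quality control for methylation beta matrices.
#
# Four checks, mirroring common array practice for germ-line methylomes:
#  * bimodality  — a good sample's beta density has prominent peaks in
#    [0, 0.2] and [0.8, 1.0] and a flat valley between; operationalized as
#    interval-mass thresholds rather than a visual density call.
#  * dlk1        — mean beta over DLK1-region sentinel CpGs; pure sperm is
#    hypomethylated there, so somatic (white blood cell) contamination
#    raises the statistic. Pass iff <= threshold (default 0.25, inclusive).
#  * intensity   — median log2 signal intensity against a floor.
#  * age confound — Welch t-test on chronological age between groups, to
#    verify age is balanced before interpreting group contrasts.

qc_result <- function(sample_id, check, pass, statistic, threshold, detail = "") {
  data.frame(sample_id = sample_id, check = check, pass = pass,
             statistic = statistic, threshold = threshold, detail = detail,
             stringsAsFactors = FALSE)
}

#' Beta-distribution bimodality check
#'
#' Computes `f_low = P(beta <= 0.2)`, `f_high = P(beta >= 0.8)` and
#' `f_mid = P(0.2 < beta < 0.8)` over one sample's beta values. The sample
#' passes iff `f_low >= p_peak`, `f_high >= p_peak` and `f_mid <= p_valley`.
#' The reported statistic is `f_mid` (the valley mass).
#'
#' @param sample_betas numeric beta vector for one sample.
#' @param p_peak minimum mass required in each peak interval (default 0.25).
#' @param p_valley maximum mass allowed in the valley (default 0.35).
#' @param min_n minimum number of beta values required (default 1000);
#'   interval masses are too noisy below this.
#' @param sample_id label carried into the result.
#' @return one-row QC result data.frame.
#' @export
bimodality_check <- function(sample_betas, p_peak = 0.25, p_valley = 0.35,
                             min_n = 1000, sample_id = NA_character_) {
  sample_betas <- sample_betas[is.finite(sample_betas)]
  if (length(sample_betas) < min_n) {
    stop(sprintf("bimodality check needs >= %d beta values (got %d)",
                 min_n, length(sample_betas)), call. = FALSE)
  }
  f_low <- mean(sample_betas <= 0.2)
  f_high <- mean(sample_betas >= 0.8)
  f_mid <- 1 - f_low - f_high
  pass <- f_low >= p_peak && f_high >= p_peak && f_mid <= p_valley
  qc_result(sample_id, "bimodality", pass, f_mid, p_valley,
            sprintf("f_low=%.3f f_high=%.3f f_mid=%.3f", f_low, f_high, f_mid))
}

#' DLK1 somatic-contamination check
#'
#' Statistic: mean beta over the DLK1-region CpGs found in the sample.
#' Passes iff the statistic is `<=` `threshold` (boundary inclusive).
#' Intended for sperm samples: DLK1 is near-unmethylated in pure sperm and
#' highly methylated in leukocytes, so the mean rises affinely with the
#' somatic mixing fraction.
#'
#' @param sample_betas named beta vector (names are CpG ids).
#' @param dlk1_cpg_ids character vector of DLK1-region CpG ids.
#' @param threshold pass threshold (default 0.25).
#' @param sample_id label carried into the result.
#' @return one-row QC result data.frame.
#' @export
dlk1_contamination_check <- function(sample_betas, dlk1_cpg_ids,
                                     threshold = 0.25,
                                     sample_id = NA_character_) {
  if (is.null(names(sample_betas))) stop("sample_betas must be named by CpG id", call. = FALSE)
  hit <- intersect(dlk1_cpg_ids, names(sample_betas))
  if (length(hit) == 0L) {
    stop("no DLK1 CpGs found in the sample: incompatible annotation", call. = FALSE)
  }
  stat <- mean(sample_betas[hit])
  qc_result(sample_id, "dlk1_contamination", stat <= threshold, stat, threshold,
            sprintf("%d DLK1 CpG(s)", length(hit)))
}

#' Median-intensity check
#'
#' Passes iff the sample's median log2 signal intensity is at least
#' `threshold`. Array scanners report this per sample; low values indicate
#' failed hybridization. Default threshold 10.5 (log2), a conventional
#' cutoff — "the standard" is scanner-dependent, so it is configurable.
#'
#' @param intensity median log2 intensity for one sample (must be >= 0).
#' @param threshold minimum acceptable value (default 10.5).
#' @param sample_id label carried into the result.
#' @return one-row QC result data.frame.
#' @export
median_intensity_check <- function(intensity, threshold = 10.5,
                                   sample_id = NA_character_) {
  assert_scalar_number(intensity, "intensity")
  if (intensity < 0) stop("negative median intensity", call. = FALSE)
  qc_result(sample_id, "median_intensity", intensity >= threshold,
            intensity, threshold)
}

#' Chronological-age confound check
#'
#' Welch (heteroscedastic) t-test on chronological age between the two
#' groups, over unique individuals. A non-significant result supports
#' interpreting group differences in epigenetic age as group effects
#' rather than age imbalance.
#'
#' @param sheet sample sheet (see [read_sample_sheet()]); each individual
#'   is counted once.
#' @param groups the two group labels to compare (default the cohort's
#'   oligozoospermic vs normozoospermic labels).
#' @return a `tsage_test` object (see [welch_ttest()]).
#' @export
age_confound_check <- function(sheet,
                               groups = c("oligozoospermic", "normozoospermic")) {
  validate_sample_sheet(sheet)
  ind <- sheet[!duplicated(sheet$individual_id), ]
  x <- ind$age_years[ind$group == groups[1]]
  y <- ind$age_years[ind$group == groups[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("age confound check needs >= 2 individuals per group", call. = FALSE)
  }
  welch_ttest(x, y, labels = groups, test_name = "age_confound")
}

#' Run all enabled sample-level QC checks and filter the matrix
#'
#' Applies the enabled checks to every sample and removes any sample that
#' fails at least one. The DLK1 check is applied to sperm samples only by
#' default (blood is legitimately methylated at the locus). When no
#' intensity table is supplied the intensity check is recorded as not
#' evaluated rather than silently passed.
#'
#' @param betas beta matrix covering the samples to screen.
#' @param sheet sample sheet annotating every column of `betas`.
#' @param dlk1_cpg_ids DLK1 annotation (character vector), or NULL to skip.
#' @param intensity optional intensity table
#'   (`sample_id`, `median_log2_intensity`).
#' @param checks which checks to run.
#' @param params named list overriding check parameters: `p_peak`,
#'   `p_valley`, `min_n`, `dlk1_threshold`, `intensity_threshold`,
#'   `dlk1_sperm_only` (default TRUE).
#' @return list with `betas` (filtered matrix), `report` (a `qc_report`:
#'   `results` data.frame, `retained`, `removed`, `reasons`).
#' @export
run_sample_qc <- function(betas, sheet, dlk1_cpg_ids = NULL, intensity = NULL,
                          checks = c("bimodality", "dlk1", "intensity"),
                          params = list()) {
  assert_beta_matrix(betas)
  validate_sample_sheet(sheet)
  checks <- match.arg(checks, several.ok = TRUE)
  unknown <- setdiff(colnames(betas), sheet$sample_id)
  if (length(unknown) > 0L) {
    stop("unannotated sample(s) in beta matrix: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  p <- utils::modifyList(list(
    p_peak = 0.25, p_valley = 0.35, min_n = 1000,
    dlk1_threshold = 0.25, intensity_threshold = 10.5,
    dlk1_sperm_only = TRUE), params)

  tissue <- sheet$tissue[match(colnames(betas), sheet$sample_id)]
  results <- list()
  for (j in seq_len(ncol(betas))) {
    sid <- colnames(betas)[j]
    col <- betas[, j]
    if ("bimodality" %in% checks) {
      results[[length(results) + 1L]] <-
        bimodality_check(col, p$p_peak, p$p_valley, p$min_n, sample_id = sid)
    }
    if ("dlk1" %in% checks && !is.null(dlk1_cpg_ids) &&
        (!p$dlk1_sperm_only || tissue[j] == "sperm")) {
      results[[length(results) + 1L]] <-
        dlk1_contamination_check(col, dlk1_cpg_ids, p$dlk1_threshold, sample_id = sid)
    }
    if ("intensity" %in% checks) {
      if (is.null(intensity)) {
        results[[length(results) + 1L]] <-
          qc_result(sid, "median_intensity", NA, NA_real_, p$intensity_threshold,
                    "not evaluated: no intensity table supplied")
      } else {
        val <- intensity$median_log2_intensity[match(sid, intensity$sample_id)]
        if (is.na(val)) {
          results[[length(results) + 1L]] <-
            qc_result(sid, "median_intensity", NA, NA_real_, p$intensity_threshold,
                      "not evaluated: sample absent from intensity table")
        } else {
          results[[length(results) + 1L]] <-
            median_intensity_check(val, p$intensity_threshold, sample_id = sid)
        }
      }
    }
  }
  results <- do.call(rbind, results)

  failed <- results[!is.na(results$pass) & !results$pass, , drop = FALSE]
  removed <- unique(failed$sample_id)
  retained <- setdiff(colnames(betas), removed)
  reasons <- if (nrow(failed) > 0L) {
    tapply(failed$check, failed$sample_id, function(x) paste(unique(x), collapse = ";"))
  } else {
    stats::setNames(character(0), character(0))
  }
  report <- structure(list(results = results, retained = retained,
                           removed = removed,
                           reasons = as.list(reasons)), class = "qc_report")
  if (length(retained) == 0L) {
    stop(paste0("all samples removed by QC (",
                paste(sprintf("%s: %s", names(reasons), unlist(reasons)),
                      collapse = "; "), ")"), call. = FALSE)
  }
  list(betas = betas[, retained, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d retained, %d removed\n",
              length(x$retained), length(x$removed)))
  if (length(x$removed) > 0L) {
    for (s in x$removed) cat(sprintf("  removed %s (%s)\n", s, x$reasons[[s]]))
  }
  invisible(x)
}

#' Write a QC report as TSV plus a JSON summary
#'
#' @param report a `qc_report`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @export
write_qc_report <- function(report, prefix) {
  stopifnot(inherits(report, "qc_report"))
  tsv <- paste0(prefix, ".tsv")
  write.table(report$results[, c("sample_id", "check", "statistic", "threshold", "pass")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(retained = report$retained, removed = report$removed,
         reasons = report$reasons),
    paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, paste0(prefix, ".json")))
}
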