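# The statistical battery: Welch two-sample t-tests on GLAD per tissue,
# the between-group test on per-individual sperm-minus-blood predicted-age
# differences, predicted-vs-chronological OLS regressions with adjusted
# r-squared, and the chronological-age confound test.
#
# Between-group comparisons are unpaired Welch tests (the two groups have
# different individuals and unequal sizes); the paired design is used only
# to construct per-individual tissue differences. All p-values are
# two-sided and unadjusted for multiplicity; a Bonferroni option exists on
# the report assembler for users who want it.

#' Welch (unequal-variance) two-sample t-test
#'
#' Computes the Welch statistic `t = (mean(x) - mean(y)) / sqrt(vx/nx +
#' vy/ny)` with Satterthwaite degrees of freedom and a two-sided p-value.
#' Degenerate zero-variance inputs are flagged rather than raised so batch
#' simulations never abort: two identical constant samples give `t = 0,
#' p = 1` by convention; constant but unequal samples give a non-finite
#' `t` with `degenerate = TRUE` and `p = NA`.
#'
#' @param x,y numeric vectors, each of length `>= 2`.
#' @param labels group labels for reporting.
#' @param test_name label carried into the result.
#' @return object of class `tsage_test` with fields `test_name`,
#'   `group_labels`, `group_means`, `group_ses`, `n`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `paired`, `degenerate`.
#' @export
welch_ttest <- function(x, y, labels = c("x", "y"), test_name = "welch_ttest") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 finite values", call. = FALSE)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  delta <- mean(x) - mean(y)
  degenerate <- se2 == 0
  if (degenerate) {
    if (delta == 0) {
      t_stat <- 0; df <- NA_real_; p <- 1
    } else {
      t_stat <- sign(delta) * Inf; df <- NA_real_; p <- NA_real_
    }
  } else {
    t_stat <- delta / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(
    test_name = test_name,
    group_labels = labels,
    group_means = stats::setNames(c(mean(x), mean(y)), labels),
    group_ses = stats::setNames(c(sqrt(vx / nx), sqrt(vy / ny)), labels),
    n = stats::setNames(c(nx, ny), labels),
    t_statistic = t_stat,
    degrees_of_freedom = df,
    p_value = p,
    paired = FALSE,
    degenerate = degenerate), class = "tsage_test")
}

#' @export
print.tsage_test <- function(x, ...) {
  cat(sprintf("<%s> %s vs %s (n = %d vs %d)\n", x$test_name,
              x$group_labels[1], x$group_labels[2], x$n[1], x$n[2]))
  cat(sprintf("  means %.4g vs %.4g (SE %.3g / %.3g)\n",
              x$group_means[1], x$group_means[2], x$group_ses[1], x$group_ses[2]))
  cat(sprintf("  t = %.4g, df = %.3g, two-sided p = %.4g%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (isTRUE(x$degenerate)) "  [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Between-group Welch test on GLAD within one tissue
#'
#' @param glad data.frame from [glad_table()].
#' @param tissue tissue to test (`"sperm"` or `"blood"`).
#' @param groups the two group labels, tested as `groups[1] - groups[2]`.
#' @return a `tsage_test`.
#' @export
glad_group_test <- function(glad, tissue,
                            groups = c("oligozoospermic", "normozoospermic")) {
  if (!tissue %in% glad$tissue) stop("unknown tissue: ", tissue, call. = FALSE)
  sub <- glad[glad$tissue == tissue, ]
  missing <- setdiff(groups, unique(sub$group))
  if (length(missing) > 0L) {
    stop("group absent in tissue '", tissue, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  welch_ttest(sub$glad[sub$group == groups[1]],
              sub$glad[sub$group == groups[2]],
              labels = groups,
              test_name = paste0(tissue, "_glad"))
}

#' Ordinary least squares of predicted on chronological age
#'
#' Fits `predicted = intercept + slope * chronological` and reports the
#' slope's two-sided p-value (t distribution, `n - 2` df), r-squared, and
#' adjusted r-squared `1 - (1 - r2) * (n - 1) / (n - 2)`. A constant
#' predicted vector yields slope 0 and r-squared 0 with a degenerate flag;
#' a perfect fit yields p = 0.
#'
#' @param chronological ages in years (non-constant, length `>= 3`).
#' @param predicted predicted ages in years.
#' @param tissue optional label carried into the result.
#' @return object of class `tsage_regression` with fields `tissue`, `n`,
#'   `slope`, `intercept`, `r_squared`, `adjusted_r_squared`,
#'   `slope_p_value`, `degenerate`.
#' @export
regression_fit <- function(chronological, predicted, tissue = NA_character_) {
  n <- length(chronological)
  if (length(predicted) != n) stop("vectors must have equal length", call. = FALSE)
  if (n < 3L) stop("regression needs n >= 3", call. = FALSE)
  if (var(chronological) == 0) stop("constant chronological ages", call. = FALSE)
  xc <- chronological - mean(chronological)
  yc <- predicted - mean(predicted)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  degenerate <- syy == 0
  slope <- sum(xc * yc) / sxx
  intercept <- mean(predicted) - slope * mean(chronological)
  rss <- syy - slope^2 * sxx
  rss <- max(rss, 0)  # guard float cancellation
  r2 <- if (degenerate) 0 else 1 - rss / syy
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  if (degenerate) {
    p <- NA_real_
  } else if (rss == 0) {
    p <- 0
  } else {
    se_slope <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * pt(-abs(slope / se_slope), n - 2)
  }
  structure(list(tissue = tissue, n = n, slope = slope, intercept = intercept,
                 r_squared = r2, adjusted_r_squared = adj_r2,
                 slope_p_value = p, degenerate = degenerate),
            class = "tsage_regression")
}

#' @export
print.tsage_regression <- function(x, ...) {
  cat(sprintf("<regression%s> n = %d: slope %.4g, intercept %.4g\n",
              if (is.na(x$tissue)) "" else paste0(" ", x$tissue), x$n,
              x$slope, x$intercept))
  cat(sprintf("  r2 = %.4g, adjusted r2 = %.4g, slope p = %.4g%s\n",
              x$r_squared, x$adjusted_r_squared, x$slope_p_value,
              if (isTRUE(x$degenerate)) "  [degenerate: constant predictor]" else ""))
  invisible(x)
}

not_evaluated <- function(reason) {
  structure(list(reason = reason), class = "tsage_not_evaluated")
}

#' @export
print.tsage_not_evaluated <- function(x, ...) {
  cat(sprintf("  not evaluated: %s\n", x$reason))
  invisible(x)
}

#' Assemble the full comparison report
#'
#' Runs the six components of the analysis battery: GLAD group tests in
#' sperm and blood, the between-group test on per-individual sperm-minus-
#' blood predicted-age differences, predicted-vs-chronological regressions
#' per tissue, and the chronological-age confound test. Components whose
#' inputs are unavailable are marked not-evaluated with the reason instead
#' of failing the whole report.
#'
#' @param glad data.frame from [glad_table()].
#' @param predictions combined prediction table (both tissues).
#' @param sheet sample sheet.
#' @param groups the two group labels (order fixes the sign of contrasts).
#' @param bonferroni if TRUE, additionally report Bonferroni-adjusted
#'   p-values (factor = number of performed tests) alongside the raw ones;
#'   raw p-values are never altered.
#' @return object of class `comparison_report` with components
#'   `sperm_glad_test`, `blood_glad_test`, `predicted_difference_test`,
#'   `sperm_regression`, `blood_regression`, `age_confound`, plus `notes`.
#' @export
run_comparisons <- function(glad, predictions, sheet,
                            groups = c("oligozoospermic", "normozoospermic"),
                            bonferroni = FALSE) {
  validate_sample_sheet(sheet)
  comp <- function(expr) tryCatch(expr, error = function(e) not_evaluated(conditionMessage(e)))

  sperm_glad_test <- comp(glad_group_test(glad, "sperm", groups))
  blood_glad_test <- comp(glad_group_test(glad, "blood", groups))

  predicted_difference_test <- comp({
    diffs <- suppressWarnings(predicted_age_difference(predictions, sheet))
    welch_ttest(diffs$difference[diffs$group == groups[1]],
                diffs$difference[diffs$group == groups[2]],
                labels = groups, test_name = "predicted_age_difference")
  })

  reg_for <- function(tis) comp({
    idx <- match(predictions$sample_id, sheet$sample_id)
    keep <- sheet$tissue[idx] == tis
    if (!any(keep)) stop("no predictions for tissue '", tis, "'")
    regression_fit(sheet$age_years[idx][keep],
                   predictions$predicted_age_years[keep], tissue = tis)
  })

  report <- structure(list(
    sperm_glad_test = sperm_glad_test,
    blood_glad_test = blood_glad_test,
    predicted_difference_test = predicted_difference_test,
    sperm_regression = reg_for("sperm"),
    blood_regression = reg_for("blood"),
    age_confound = comp(age_confound_check(sheet, groups)),
    notes = paste("Between-group tests are unpaired Welch t-tests;",
                  "pairing is used only to form per-individual",
                  "sperm-minus-blood differences. P-values are two-sided",
                  "and unadjusted.")), class = "comparison_report")
  if (bonferroni) {
    k <- sum(vapply(report[1:6], inherits, logical(1), "tsage_test"))
    for (nm in names(report)[1:6]) {
      if (inherits(report[[nm]], "tsage_test")) {
        report[[nm]]$p_bonferroni <- min(1, report[[nm]]$p_value * k)
      }
    }
    report$notes <- paste(report$notes, sprintf(
      "Bonferroni-adjusted p-values use factor %d.", k))
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== comparison report ==\n")
  for (nm in c("sperm_glad_test", "blood_glad_test", "predicted_difference_test",
               "sperm_regression", "blood_regression", "age_confound")) {
    cat(nm, ":\n", sep = "")
    print(x[[nm]])
  }
  cat("notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Flatten a comparison report to one row per test
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return data.frame with columns `test`, `group_a_mean`, `group_b_mean`,
#'   `t`, `df`, `p` (tests) and `test`, `slope`, `adjusted_r_squared`, `p`
#'   filled for regressions.
#' @export
as.data.frame.comparison_report <- function(x, ...) {
  rows <- lapply(c("sperm_glad_test", "blood_glad_test",
                   "predicted_difference_test", "age_confound",
                   "sperm_regression", "blood_regression"), function(nm) {
    obj <- x[[nm]]
    if (inherits(obj, "tsage_test")) {
      data.frame(test = nm, group_a_mean = unname(obj$group_means[1]),
                 group_b_mean = unname(obj$group_means[2]),
                 slope = NA_real_, adjusted_r_squared = NA_real_,
                 t = obj$t_statistic, df = obj$degrees_of_freedom,
                 p = obj$p_value, stringsAsFactors = FALSE)
    } else if (inherits(obj, "tsage_regression")) {
      data.frame(test = nm, group_a_mean = NA_real_, group_b_mean = NA_real_,
                 slope = obj$slope, adjusted_r_squared = obj$adjusted_r_squared,
                 t = NA_real_, df = obj$n - 2, p = obj$slope_p_value,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(test = nm, group_a_mean = NA_real_, group_b_mean = NA_real_,
                 slope = NA_real_, adjusted_r_squared = NA_real_,
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write a comparison report as JSON, Markdown and TSV
#'
#' @param report a `comparison_report`.
#' @param prefix path prefix; writes `<prefix>.json`, `<prefix>.md`,
#'   `<prefix>.tsv`.
#' @export
write_comparison_report <- function(report, prefix) {
  stopifnot(inherits(report, "comparison_report"))
  df <- as.data.frame(report)
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  to_plain <- function(obj) {
    if (inherits(obj, "tsage_not_evaluated")) {
      list(not_evaluated = TRUE, reason = obj$reason)
    } else {
      unclass(obj)
    }
  }
  jsonlite::write_json(
    c(lapply(report[setdiff(names(report), "notes")], to_plain),
      list(notes = report$notes)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Comparison report", "",
          report$notes, "",
          "| test | group A mean | group B mean | slope | adj. r2 | t | df | p |",
          "|---|---|---|---|---|---|---|---|",
          apply(df, 1, function(r) {
            paste0("| ", paste(vapply(r, function(v) {
              if (is.na(v) || v == "NA") "" else format(v, digits = 4)
            }, character(1)), collapse = " | "), " |")
          }))
  writeLines(md, paste0(prefix, ".md"))
  invisible(paste0(prefix, c(".json", ".md", ".tsv")))
}
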