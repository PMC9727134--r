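# Linear methylation clocks: coefficient files, age transforms, prediction.
#
# A clock is a linear score over CpG beta values,
#   m = intercept + sum_i coef_i * beta_i,
# mapped to years through an age transform. Somatic clocks trained on
# transformed age use the piecewise log-linear "adult age" convention;
# clocks trained directly in years use the identity transform.

#' Construct an age transform
#'
#' Two transforms are supported. `"identity"` leaves the linear score in
#' years. `"log-adult"` is the piecewise convention used by the standard
#' somatic (blood) calculator: the clock is linear in
#' `log((age+1)/(adult+1))` for ages up to `adult_age` and linear in
#' `(age - adult)/(adult+1)` above it, which compresses pediatric ages.
#'
#' @param type `"identity"` or `"log-adult"`. A compact spec string such as
#'   `"log-adult:20"` is also accepted (the number sets `adult_age`).
#' @param adult_age breakpoint in years for the log-adult transform;
#'   must be positive. Default 20, the published convention.
#' @return an object of class `age_transform`.
#' @examples
#' tr <- age_transform("log-adult", 20)
#' inverse_age_transform(0, tr)   # 20
#' inverse_age_transform(1, tr)   # 41
#' @export
age_transform <- function(type = c("identity", "log-adult"), adult_age = 20) {
  if (length(type) == 1L && grepl(":", type, fixed = TRUE)) {
    parts <- strsplit(type, ":", fixed = TRUE)[[1]]
    type <- parts[1]
    adult_age <- as.numeric(parts[2])
  }
  type <- match.arg(type)
  if (type == "log-adult") {
    assert_scalar_number(adult_age, "adult_age")
    if (adult_age <= 0) stop("adult_age must be > 0", call. = FALSE)
  }
  structure(list(type = type, adult_age = adult_age), class = "age_transform")
}

as_age_transform <- function(x) {
  if (inherits(x, "age_transform")) return(x)
  if (is.character(x) && length(x) == 1L) return(age_transform(x))
  if (is.list(x) && !is.null(x$type)) {
    return(age_transform(x$type, x$adult_age %||% 20))
  }
  stop("cannot interpret transform spec", call. = FALSE)
}

#' Forward and inverse age transforms
#'
#' `forward_age_transform()` maps age in years to the clock's linear scale;
#' `inverse_age_transform()` maps a linear score back to years. They are
#' exact inverses of each other on the whole real line.
#'
#' @param age,m numeric vector of ages (years) / linear scores.
#' @param transform an [age_transform()] (or spec accepted by it).
#' @return numeric vector.
#' @export
forward_age_transform <- function(age, transform) {
  transform <- as_age_transform(transform)
  if (transform$type == "identity") return(age)
  adult <- transform$adult_age
  ifelse(age <= adult,
         log((age + 1) / (adult + 1)),
         (age - adult) / (adult + 1))
}

#' @rdname forward_age_transform
#' @export
inverse_age_transform <- function(m, transform) {
  transform <- as_age_transform(transform)
  if (transform$type == "identity") return(m)
  adult <- transform$adult_age
  ifelse(m < 0,
         (adult + 1) * exp(m) - 1,
         (adult + 1) * m + adult)
}

#' Construct a clock model
#'
#' @param coefficients named numeric vector, CpG id -> weight per beta unit.
#'   May be empty only when `allow_intercept_only = TRUE` (a constant
#'   predictor, occasionally useful as a null baseline).
#' @param intercept intercept on the transformed-age scale.
#' @param transform an [age_transform()] or spec string.
#' @param name label used in output tables.
#' @param allow_intercept_only permit a clock with no CpG terms.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(coefficients, intercept, transform = "identity",
                        name = "clock", allow_intercept_only = FALSE) {
  assert_scalar_number(intercept, "intercept")
  transform <- as_age_transform(transform)
  if (length(coefficients) == 0L) {
    if (!allow_intercept_only) {
      stop("clock has no CpGs (set allow_intercept_only = TRUE for a constant predictor)",
           call. = FALSE)
    }
    coefficients <- stats::setNames(numeric(0), character(0))
  } else {
    if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
      stop("coefficients must be named by CpG id", call. = FALSE)
    }
    if (anyDuplicated(names(coefficients))) {
      stop("duplicate CpG id in clock coefficients", call. = FALSE)
    }
    if (any(!is.finite(coefficients))) stop("non-finite clock coefficient", call. = FALSE)
  }
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients, transform = transform),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  tr <- if (x$transform$type == "identity") "identity" else
    sprintf("log-adult (adult_age = %g)", x$transform$adult_age)
  cat(sprintf("<clock_model> %s: %d CpG(s), intercept %.4g, transform %s\n",
              x$name, length(x$coefficients), x$intercept, tr))
  invisible(x)
}

#' Load a clock coefficient file
#'
#' Expects a CSV with columns `cpg_id,coefficient` containing exactly one
#' `(Intercept)` row; every other row is one CpG weight. Duplicated CpG
#' rows and non-numeric coefficients are rejected.
#'
#' @param path CSV file path.
#' @param transform transform spec (see [age_transform()]), e.g.
#'   `"identity"` or `"log-adult:20"`.
#' @param name clock label; defaults to the file name.
#' @param allow_intercept_only see [clock_model()].
#' @return a `clock_model`.
#' @export
load_clock <- function(path, transform = "identity",
                       name = tools::file_path_sans_ext(basename(path)),
                       allow_intercept_only = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("cpg_id", "coefficient") %in% names(df))) {
    stop("clock file must have columns 'cpg_id' and 'coefficient'", call. = FALSE)
  }
  coefs <- suppressWarnings(as.numeric(df$coefficient))
  if (any(is.na(coefs))) {
    stop("non-numeric coefficient in clock file: ",
         df$cpg_id[which(is.na(coefs))[1]], call. = FALSE)
  }
  is_int <- df$cpg_id == "(Intercept)"
  if (sum(is_int) != 1L) {
    stop("clock file must contain exactly one '(Intercept)' row (found ",
         sum(is_int), ")", call. = FALSE)
  }
  cpg <- df$cpg_id[!is_int]
  if (anyDuplicated(cpg)) {
    stop("duplicate CpG id in clock file: ", cpg[duplicated(cpg)][1], call. = FALSE)
  }
  if (length(cpg) == 0L && !allow_intercept_only) {
    stop("clock file has no CpGs", call. = FALSE)
  }
  clock_model(stats::setNames(coefs[!is_int], cpg), intercept = coefs[is_int],
              transform = transform, name = name,
              allow_intercept_only = allow_intercept_only)
}

#' Write a clock model to CSV
#'
#' Inverse of [load_clock()]: emits `cpg_id,coefficient` with a reserved
#' `(Intercept)` row. The transform is not stored in the file (it is part
#' of the calling convention, as with the public calculators).
#' @param clock a `clock_model`.
#' @param path output CSV path.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  df <- data.frame(
    cpg_id = c("(Intercept)", names(clock$coefficients)),
    coefficient = c(clock$intercept, unname(clock$coefficients)),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict epigenetic age for every sample in a beta matrix
#'
#' Computes the linear score `m = intercept + sum coef_i * beta_i` over the
#' clock's CpGs and maps it to years via the clock's transform. Beta values
#' outside \[0,1\] by more than 1e-6 abort; smaller excursions are clamped.
#'
#' Missing-CpG policy:
#' * `"fail"` (default): any clock CpG absent from the matrix aborts with
#'   the missing-CpG list. Silent imputation distorts age acceleration, so
#'   imputation is strictly opt-in.
#' * `"mean"`: a missing CpG is imputed, per sample, with the mean beta of
#'   the clock CpGs that are present in that sample.
#' * `"reference"`: missing CpGs take values from `reference` (a named
#'   numeric vector or a CSV with columns `cpg_id,beta`); a clock CpG
#'   absent from the reference aborts.
#'
#' @param clock a `clock_model`.
#' @param betas beta matrix (CpG rownames, sample colnames).
#' @param missing one of `"fail"`, `"mean"`, `"reference"`.
#' @param reference named numeric vector or CSV path (for `"reference"`).
#' @param sheet optional sample sheet; if supplied, tissue labels are
#'   joined onto the output.
#' @return data.frame with columns `sample_id`, `tissue`,
#'   `predicted_age_years`, `n_cpgs_used`, `n_cpgs_imputed`.
#' @export
apply_clock <- function(clock, betas, missing = c("fail", "mean", "reference"),
                        reference = NULL, sheet = NULL) {
  stopifnot(inherits(clock, "clock_model"))
  assert_beta_matrix(betas)
  missing <- match.arg(missing)
  betas[] <- clamp01(betas)

  cpgs <- names(clock$coefficients)
  present <- intersect(cpgs, rownames(betas))
  absent <- setdiff(cpgs, present)
  n_samples <- ncol(betas)

  if (length(absent) > 0L && missing == "fail") {
    stop(sprintf("%d clock CpG(s) missing from beta matrix: %s%s",
                 length(absent), paste(head(absent, 5), collapse = ", "),
                 if (length(absent) > 5) ", ..." else ""), call. = FALSE)
  }

  sub <- betas[present, , drop = FALSE]
  m <- rep(clock$intercept, n_samples)
  if (length(present) > 0L) {
    m <- m + as.numeric(crossprod(sub, clock$coefficients[present]))
  }
  if (length(absent) > 0L) {
    if (missing == "mean") {
      if (length(present) == 0L) {
        stop("cannot mean-impute: no clock CpGs present in the matrix", call. = FALSE)
      }
      fill <- colMeans(sub)  # per-sample mean over present clock CpGs
      m <- m + sum(clock$coefficients[absent]) * fill
    } else { # reference
      if (is.character(reference) && length(reference) == 1L) {
        ref_df <- read.csv(reference, stringsAsFactors = FALSE)
        stopifnot(all(c("cpg_id", "beta") %in% names(ref_df)))
        reference <- stats::setNames(as.numeric(ref_df$beta), ref_df$cpg_id)
      }
      if (is.null(reference)) stop("missing = 'reference' requires a reference", call. = FALSE)
      no_ref <- setdiff(absent, names(reference))
      if (length(no_ref) > 0L) {
        stop("CpG(s) absent from imputation reference: ",
             paste(head(no_ref, 5), collapse = ", "), call. = FALSE)
      }
      m <- m + sum(clock$coefficients[absent] * clamp01(reference[absent]))
    }
  }

  out <- data.frame(
    sample_id = colnames(betas),
    tissue = NA_character_,
    predicted_age_years = inverse_age_transform(m, clock$transform),
    n_cpgs_used = length(cpgs),
    n_cpgs_imputed = length(absent),
    stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    idx <- match(out$sample_id, sheet$sample_id)
    out$tissue <- sheet$tissue[idx]
  }
  out
}
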