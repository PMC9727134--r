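# Synthetic paired-tissue methylome generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# bimodal beta distributions (peaks in [0,0.2] and [0.8,1.0], flat valley
# between), clock CpGs that drift linearly with age, DLK1-region CpGs that
# are hypomethylated in pure sperm and highly methylated in blood (so
# somatic contamination raises their mean), and a two-group cohort in which
# the case group's sperm ages faster than chronology while blood does not.
# Each generated clock ships with its analytic inverse ("true clock"), so
# parameter recovery is exact in the noise-free limit.

#' Simulation configuration
#'
#' Defaults encode the study design the package targets: 10 oligozoospermic
#' vs 24 normozoospermic men, chronological ages 32.73 +/- 1.9 (SE) and
#' 31.64 +/- 1.3 (SE) years respectively, one sperm and one blood sample
#' per individual. Cohort-age SE is converted to an individual-level SD via
#' `SD = SE * sqrt(n)` so the configured SE is recovered in expectation;
#' ages are truncated to \[18, 60\].
#'
#' Age acceleration is multiplicative: the effective (biological) age of a
#' tissue-sample is `chronological * (1 + accel)`, so the GLAD ratio
#' statistic directly targets `accel`.
#'
#' Clock-CpG trajectories are `beta = b0 + s * effective_age` with
#' baselines and slopes drawn once per clock: half the CpGs start low
#' (`b0` in `baseline_low`) and gain methylation (`s` in `+slope_range`),
#' half start high (`baseline_high`) and lose it (`-slope_range`). The
#' default ranges keep noise-free trajectories inside \[0,1\] over the full
#' age span, so clipping never distorts the linear model.
#'
#' @param n_oligo,n_normo individuals per group.
#' @param age_mean_oligo,age_se_oligo,age_mean_normo,age_se_normo cohort
#'   age summaries in years (mean and standard error).
#' @param n_clock_cpgs clock CpGs per tissue clock.
#' @param n_background_cpgs bimodal background CpGs (shared across tissues).
#' @param n_dlk1_cpgs DLK1-region sentinel CpGs.
#' @param sperm_accel_oligo,blood_accel_oligo fractional age acceleration
#'   applied to the oligozoospermic group in each tissue (must be > -1).
#' @param beta_noise_sd additive Gaussian noise SD on clock-CpG betas.
#'   The default 0.13 is calibrated so a 50-CpG clock predicts age with an
#'   error SD of roughly 3.5 years, the accuracy scale reported for
#'   methylation clocks of this size.
#' @param background_noise_sd per-sample technical noise on background and
#'   DLK1 CpGs (smaller: no biological age signal there).
#' @param contamination_fraction somatic (blood) mixing weight applied to
#'   every sperm sample; 0 = pure sperm.
#' @param age_range truncation bounds for chronological age (years).
#' @param slope_range absolute per-year slope range for clock CpGs.
#' @param baseline_low,baseline_high baseline (age-0) beta ranges for
#'   gaining / losing clock CpGs.
#' @param seed integer RNG seed; same config + seed reproduces the cohort
#'   byte-for-byte.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_oligo = 10, n_normo = 24,
                       age_mean_oligo = 32.73, age_se_oligo = 1.9,
                       age_mean_normo = 31.64, age_se_normo = 1.3,
                       n_clock_cpgs = 50, n_background_cpgs = 5000,
                       n_dlk1_cpgs = 5,
                       sperm_accel_oligo = 0, blood_accel_oligo = 0,
                       beta_noise_sd = 0.13, background_noise_sd = 0.03,
                       contamination_fraction = 0,
                       age_range = c(18, 60),
                       slope_range = c(0.002, 0.008),
                       baseline_low = c(0.15, 0.35),
                       baseline_high = c(0.65, 0.85),
                       seed = 1L) {
  cfg <- list(
    n_oligo = assert_count(n_oligo, "n_oligo"),
    n_normo = assert_count(n_normo, "n_normo"),
    age_mean_oligo = age_mean_oligo, age_se_oligo = age_se_oligo,
    age_mean_normo = age_mean_normo, age_se_normo = age_se_normo,
    n_clock_cpgs = assert_count(n_clock_cpgs, "n_clock_cpgs"),
    n_background_cpgs = assert_count(n_background_cpgs, "n_background_cpgs"),
    n_dlk1_cpgs = assert_count(n_dlk1_cpgs, "n_dlk1_cpgs"),
    sperm_accel_oligo = sperm_accel_oligo,
    blood_accel_oligo = blood_accel_oligo,
    beta_noise_sd = beta_noise_sd,
    background_noise_sd = background_noise_sd,
    contamination_fraction = contamination_fraction,
    age_range = age_range,
    slope_range = slope_range,
    baseline_low = baseline_low, baseline_high = baseline_high,
    seed = as.integer(seed))
  for (nm in c("age_se_oligo", "age_se_normo", "beta_noise_sd", "background_noise_sd")) {
    assert_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  for (nm in c("sperm_accel_oligo", "blood_accel_oligo")) {
    assert_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] <= -1) stop(sprintf("'%s' must be > -1", nm), call. = FALSE)
  }
  assert_scalar_number(cfg$contamination_fraction, "contamination_fraction")
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction > 1) {
    stop("'contamination_fraction' must be in [0,1]", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] <= 0 || diff(age_range) <= 0) {
    stop("'age_range' must be increasing positive bounds", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d oligozoospermic + %d normozoospermic individuals\n",
    "  CpGs: %d clock/tissue, %d background, %d DLK1\n",
    "  sperm accel (oligo) %.3f, blood accel (oligo) %.3f, noise sd %.3f, seed %d\n"),
    x$n_oligo, x$n_normo, x$n_clock_cpgs, x$n_background_cpgs, x$n_dlk1_cpgs,
    x$sperm_accel_oligo, x$blood_accel_oligo, x$beta_noise_sd, x$seed))
  invisible(x)
}

# DLK1 sentinel levels: hypomethylated in pure sperm, high in blood
DLK1_SPERM_MEAN <- 0.05
DLK1_BLOOD_MEAN <- 0.80

draw_clock_params <- function(k, slope_range, baseline_low, baseline_high) {
  n_gain <- ceiling(k / 2)
  sign <- c(rep(1, n_gain), rep(-1, k - n_gain))
  s <- sign * runif(k, slope_range[1], slope_range[2])
  b0 <- ifelse(sign > 0,
               runif(k, baseline_low[1], baseline_low[2]),
               runif(k, baseline_high[1], baseline_high[2]))
  list(baselines = b0, slopes = s)
}

# Refuse generative regimes where the linear model saturates the unit
# interval: if > 1% of noise-free clock-CpG values at the extreme ages fall
# outside [0,1], clipping would bend the model the true clock inverts.
check_saturation <- function(params, max_age, min_age) {
  vals <- c(params$baselines + params$slopes * max_age,
            params$baselines + params$slopes * min_age)
  frac <- mean(vals < 0 | vals > 1)
  if (frac > 0.01) {
    stop(sprintf(paste0(
      "unusable generative regime: %.1f%% of noise-free clock-CpG values at ",
      "ages [%g, %g] fall outside [0,1]; narrow slope/baseline ranges"),
      100 * frac, min_age, max_age), call. = FALSE)
  }
  invisible(frac)
}

#' Build the analytic inverse of a linear clock-CpG generative model
#'
#' Given per-CpG baselines and slopes of `beta_i = b0_i + s_i * age`, the
#' least-squares inversion for age given an observed beta vector is
#' `age = sum_i s_i (beta_i - b0_i) / sum_i s_i^2`, i.e. a linear clock with
#' coefficient `s_i / sum(s^2)` on CpG i and intercept
#' `-sum(s_i b0_i) / sum(s^2)`, under the identity transform. On noise-free
#' data the residual is exactly 0; under i.i.d. beta noise the prediction
#' error SD scales as `1/sqrt(k)` in the number of CpGs.
#'
#' @param baselines,slopes numeric vectors (slopes all nonzero).
#' @param cpg_ids CpG identifiers, same length.
#' @param name clock label.
#' @return a `clock_model` with identity transform.
#' @export
build_true_clock <- function(baselines, slopes, cpg_ids, name = "true_clock") {
  k <- length(slopes)
  if (length(baselines) != k || length(cpg_ids) != k || k == 0L) {
    stop("baselines, slopes and cpg_ids must have equal positive length", call. = FALSE)
  }
  if (any(slopes == 0) || sum(slopes^2) == 0) {
    stop("degenerate slope set: slopes must be nonzero", call. = FALSE)
  }
  denom <- sum(slopes^2)
  coefs <- stats::setNames(slopes / denom, cpg_ids)
  clock_model(coefs, intercept = -sum(slopes * baselines) / denom,
              transform = "identity", name = name)
}

#' Mix a sperm beta profile with a blood profile
#'
#' Models white-blood-cell contamination of a semen sample as a convex
#' combination: `(1 - fraction) * sperm + fraction * blood`, elementwise
#' over a shared CpG set. With named vectors the blood profile is aligned
#' to the sperm CpG ids; the CpG sets must match.
#'
#' @param sperm_profile,blood_profile numeric beta vectors over the same
#'   CpGs (named or positionally aligned).
#' @param fraction somatic mixing weight in \[0,1\].
#' @return mixed beta vector (named like `sperm_profile`).
#' @export
mix_contamination <- function(sperm_profile, blood_profile, fraction) {
  assert_scalar_number(fraction, "fraction")
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0,1]", call. = FALSE)
  if (!is.null(names(sperm_profile)) && !is.null(names(blood_profile))) {
    if (!setequal(names(sperm_profile), names(blood_profile))) {
      stop("mismatched CpG sets between sperm and blood profiles", call. = FALSE)
    }
    blood_profile <- blood_profile[names(sperm_profile)]
  } else if (length(sperm_profile) != length(blood_profile)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  (1 - fraction) * sperm_profile + fraction * blood_profile
}

#' Generate a paired-tissue synthetic cohort
#'
#' Draws chronological ages per group, builds one sperm and one blood
#' beta matrix over a shared CpG universe (both tissue clocks' CpGs,
#' bimodal background CpGs, DLK1 sentinels), applies the configured age
#' acceleration to the oligozoospermic group, optionally mixes somatic
#' contamination into every sperm sample, and returns the matching "true"
#' clocks plus the per-sample effective ages used to generate the data.
#'
#' Within its own tissue a clock CpG follows `b0 + s * effective_age`; in
#' the other tissue it sits flat at its mid-trajectory level (`b0 + 35 s`),
#' so somatic contamination attenuates the sperm clock's age signal toward
#' a constant — the failure mode the DLK1 check exists to catch.
#' Background CpGs get a per-CpG archetype level drawn from a bimodal
#' mixture (45% low ~ Beta(2,28), 45% high ~ Beta(28,2), 10% intermediate
#' ~ Beta(2,2)) shared by both tissues, plus per-sample technical noise.
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_bundle`: list with `sperm_betas`,
#'   `blood_betas`, `sheet`, `true_sperm_clock`, `true_blood_clock`,
#'   `truth` (sample_id, tissue, effective_age), `dlk1_ids`, `intensity`
#'   (per-sample median log2 intensity summaries), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_o <- cfg$n_oligo; n_n <- cfg$n_normo
  n_ind <- n_o + n_n

  # cohort-level SE -> individual SD
  ages <- c(
    rtruncnorm(n_o, cfg$age_mean_oligo, cfg$age_se_oligo * sqrt(n_o),
               cfg$age_range[1], cfg$age_range[2]),
    rtruncnorm(n_n, cfg$age_mean_normo, cfg$age_se_normo * sqrt(n_n),
               cfg$age_range[1], cfg$age_range[2]))
  ind_id <- c(sprintf("O%02d", seq_len(n_o)), sprintf("N%02d", seq_len(n_n)))
  group <- rep(c("oligozoospermic", "normozoospermic"), c(n_o, n_n))

  sheet <- data.frame(
    sample_id = c(paste0(ind_id, "_sperm"), paste0(ind_id, "_blood")),
    individual_id = rep(ind_id, 2),
    tissue = rep(c("sperm", "blood"), each = n_ind),
    group = rep(group, 2),
    age_years = rep(ages, 2),
    stringsAsFactors = FALSE)

  is_oligo <- group == "oligozoospermic"
  eff_sperm <- ages * (1 + ifelse(is_oligo, cfg$sperm_accel_oligo, 0))
  eff_blood <- ages * (1 + ifelse(is_oligo, cfg$blood_accel_oligo, 0))

  max_eff <- cfg$age_range[2] * (1 + max(cfg$sperm_accel_oligo, cfg$blood_accel_oligo, 0))
  k <- cfg$n_clock_cpgs
  sperm_par <- draw_clock_params(k, cfg$slope_range, cfg$baseline_low, cfg$baseline_high)
  blood_par <- draw_clock_params(k, cfg$slope_range, cfg$baseline_low, cfg$baseline_high)
  check_saturation(sperm_par, max_eff, cfg$age_range[1])
  check_saturation(blood_par, max_eff, cfg$age_range[1])

  sperm_clock_ids <- sprintf("cgS%05d", seq_len(k))
  blood_clock_ids <- sprintf("cgB%05d", seq_len(k))
  bg_ids <- sprintf("cgX%06d", seq_len(cfg$n_background_cpgs))
  dlk1_ids <- sprintf("cgDLK1_%02d", seq_len(cfg$n_dlk1_cpgs))
  all_ids <- c(sperm_clock_ids, blood_clock_ids, bg_ids, dlk1_ids)

  # background archetype levels: bimodal mixture shared by both tissues
  comp <- sample.int(3L, cfg$n_background_cpgs, replace = TRUE,
                     prob = c(0.45, 0.45, 0.10))
  bg_level <- numeric(cfg$n_background_cpgs)
  bg_level[comp == 1L] <- rbeta(sum(comp == 1L), 2, 28)
  bg_level[comp == 2L] <- rbeta(sum(comp == 2L), 28, 2)
  bg_level[comp == 3L] <- rbeta(sum(comp == 3L), 2, 2)

  clock_block <- function(par, eff_age) {
    m <- par$baselines + outer(par$slopes, eff_age)
    if (cfg$beta_noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, cfg$beta_noise_sd), nrow = nrow(m))
    }
    clip01(m)
  }
  flat_block <- function(par, n) {
    lev <- par$baselines + 35 * par$slopes  # mid-trajectory, age-flat
    m <- matrix(lev, nrow = length(lev), ncol = n)
    if (cfg$beta_noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, cfg$beta_noise_sd), nrow = nrow(m))
    }
    clip01(m)
  }
  noise_block <- function(level, n, sd) {
    m <- matrix(level, nrow = length(level), ncol = n)
    if (sd > 0) m <- m + matrix(rnorm(length(m), 0, sd), nrow = nrow(m))
    clip01(m)
  }

  build_tissue <- function(own_par, own_first, eff_age, dlk1_mean, ids) {
    own <- clock_block(own_par, eff_age)
    other <- flat_block(if (own_first) blood_par else sperm_par, n_ind)
    bg <- noise_block(bg_level, n_ind, cfg$background_noise_sd)
    dlk1 <- noise_block(rep(dlk1_mean, cfg$n_dlk1_cpgs), n_ind,
                        cfg$background_noise_sd)
    m <- if (own_first) rbind(own, other, bg, dlk1) else rbind(other, own, bg, dlk1)
    dimnames(m) <- list(all_ids, ids)
    m
  }

  sperm_betas <- build_tissue(sperm_par, TRUE, eff_sperm,
                              DLK1_SPERM_MEAN, paste0(ind_id, "_sperm"))
  blood_betas <- build_tissue(blood_par, FALSE, eff_blood,
                              DLK1_BLOOD_MEAN, paste0(ind_id, "_blood"))

  if (cfg$contamination_fraction > 0) {
    f <- cfg$contamination_fraction
    sperm_betas <- (1 - f) * sperm_betas + f * blood_betas[, , drop = FALSE]
    colnames(sperm_betas) <- paste0(ind_id, "_sperm")
  }

  intensity <- data.frame(
    sample_id = sheet$sample_id,
    median_log2_intensity = rnorm(nrow(sheet), 12, 0.5),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = sheet$sample_id,
    tissue = sheet$tissue,
    effective_age = c(eff_sperm, eff_blood),
    stringsAsFactors = FALSE)

  structure(list(
    sperm_betas = sperm_betas,
    blood_betas = blood_betas,
    sheet = sheet,
    true_sperm_clock = build_true_clock(sperm_par$baselines, sperm_par$slopes,
                                        sperm_clock_ids, "true_sperm_clock"),
    true_blood_clock = build_true_clock(blood_par$baselines, blood_par$slopes,
                                        blood_clock_ids, "true_blood_clock"),
    truth = truth,
    dlk1_ids = dlk1_ids,
    intensity = intensity,
    config = cfg), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_bundle> %d individuals (%d oligozoospermic, %d normozoospermic)\n",
    "  %d CpGs x %d samples per tissue matrix; seed %d\n"),
    length(unique(x$sheet$individual_id)), x$config$n_oligo, x$config$n_normo,
    nrow(x$sperm_betas), ncol(x$sperm_betas), x$config$seed))
  invisible(x)
}

#' Persist a synthetic cohort as plain-text files
#'
#' Writes the two beta matrices (TSV), the sample sheet (CSV), both true
#' clock coefficient files (CSV), the DLK1 annotation, the intensity table,
#' and a JSON sidecar recording the configuration, seed and per-sample
#' effective-age truth.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    sperm_betas = p("sperm_betas.tsv"), blood_betas = p("blood_betas.tsv"),
    sheet = p("sample_sheet.csv"),
    sperm_clock = p("clock_sperm.csv"), blood_clock = p("clock_blood.csv"),
    dlk1 = p("dlk1_cpgs.txt"), intensity = p("intensity.tsv"),
    meta = p("sim_meta.json"))
  write_beta_matrix(bundle$sperm_betas, paths["sperm_betas"])
  write_beta_matrix(bundle$blood_betas, paths["blood_betas"])
  write_sample_sheet(bundle$sheet, paths["sheet"])
  write_clock(bundle$true_sperm_clock, paths["sperm_clock"])
  write_clock(bundle$true_blood_clock, paths["blood_clock"])
  write_cpg_list(bundle$dlk1_ids, paths["dlk1"])
  write_intensity_table(bundle$intensity, paths["intensity"])
  meta <- list(config = unclass(bundle$config), seed = bundle$config$seed,
               truth = bundle$truth)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
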