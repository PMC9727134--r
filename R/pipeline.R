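# Pipeline orchestration: simulate/load -> qc -> predict -> glad -> compare.
#
# Every stage consumes and produces plain-text files, so any stage can be
# rerun standalone from persisted intermediates. A single global seed
# derives per-stage substreams deterministically; identical config + seed
# reproduces byte-identical tables.

#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()]: synthetic mode) or `inputs`
#' (named list of file paths: real-data mode) must be supplied. In
#' real-data mode `inputs` must name `sperm_betas`, `blood_betas`, `sheet`,
#' `sperm_clock`, `blood_clock` and may name `dlk1`, `intensity`,
#' `sperm_transform`, `blood_transform` (transform specs, default
#' `"identity"` for sperm and `"log-adult:20"` for blood).
#'
#' @param sim optional [sim_config()].
#' @param inputs optional named list of input file paths.
#' @param qc named list of QC settings passed to [run_sample_qc()]
#'   (`checks`, `params`); set `checks = character(0)` to disable QC.
#' @param glad named list: `scope` and `form` for [glad_table()].
#' @param seed global seed; defaults to `sim$seed` in synthetic mode.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL,
                            qc = list(), glad = list(), seed = NULL) {
  if (is.null(sim) == is.null(inputs)) {
    stop("supply exactly one of 'sim' (synthetic mode) or 'inputs' (file mode)",
         call. = FALSE)
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    seed <- seed %||% sim$seed
  } else {
    need <- c("sperm_betas", "blood_betas", "sheet", "sperm_clock", "blood_clock")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0L) {
      stop("inputs missing: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    seed <- seed %||% 1L
  }
  structure(list(sim = sim, inputs = inputs,
                 qc = qc, glad = glad, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_paths <- function(out_dir) {
  list(
    simulate = file.path(out_dir, "simulate"),
    qc = file.path(out_dir, "qc"),
    predict = file.path(out_dir, "predict"),
    glad = file.path(out_dir, "glad"),
    compare = file.path(out_dir, "compare"))
}

#' Run the full pipeline
#'
#' Executes simulate (or input staging), QC, clock prediction, GLAD and the
#' comparison battery, persisting every intermediate table under
#' `out_dir/<stage>/`, writing per-tissue predicted-vs-chronological
#' scatterplots, and recording a manifest with per-file MD5 checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir writable output directory.
#' @return list with `manifest` (data.frame of files + checksums, plus
#'   attributes) and `report` (the `comparison_report`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable", call. = FALSE)
  sp <- stage_paths(out_dir)
  for (d in sp) dir.create(d, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # stage 1: simulate, or stage the supplied input files
  files <- run_stage("simulate", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$seed, 1L)
      paths <- write_cohort(generate_cohort(cfg), sp$simulate)
      c(paths,
        sperm_transform = "identity", blood_transform = "identity")
    } else {
      inp <- config$inputs
      c(sperm_betas = inp$sperm_betas, blood_betas = inp$blood_betas,
        sheet = inp$sheet, sperm_clock = inp$sperm_clock,
        blood_clock = inp$blood_clock,
        dlk1 = inp$dlk1 %||% NA, intensity = inp$intensity %||% NA,
        sperm_transform = inp$sperm_transform %||% "identity",
        blood_transform = inp$blood_transform %||% "log-adult:20")
    }
  })

  # stage 2: QC (reads the persisted stage-1 files)
  run_stage("qc", {
    sheet <- read_sample_sheet(files[["sheet"]])
    dlk1 <- if (!is.na(files[["dlk1"]])) read_cpg_list(files[["dlk1"]]) else NULL
    intensity <- if (!is.na(files[["intensity"]])) read_intensity_table(files[["intensity"]]) else NULL
    checks <- config$qc$checks %||% c("bimodality", "dlk1", "intensity")
    for (tis in c("sperm", "blood")) {
      betas <- read_beta_matrix(files[[paste0(tis, "_betas")]])
      if (length(checks) == 0L) {
        filtered <- list(betas = betas,
                         report = structure(list(results = NULL,
                                                 retained = colnames(betas),
                                                 removed = character(0),
                                                 reasons = list()),
                                            class = "qc_report"))
      } else {
        filtered <- run_sample_qc(betas, sheet, dlk1_cpg_ids = dlk1,
                                  intensity = intensity, checks = checks,
                                  params = config$qc$params %||% list())
      }
      write_beta_matrix(filtered$betas,
                        file.path(sp$qc, paste0(tis, "_betas_filtered.tsv")))
      if (!is.null(filtered$report$results)) {
        write_qc_report(filtered$report, file.path(sp$qc, paste0(tis, "_qc")))
      }
    }
  })

  # stage 3: clock prediction on QC-filtered matrices
  predictions <- run_stage("predict", {
    sheet <- read_sample_sheet(files[["sheet"]])
    preds <- lapply(c("sperm", "blood"), function(tis) {
      clock <- load_clock(files[[paste0(tis, "_clock")]],
                          transform = files[[paste0(tis, "_transform")]])
      betas <- read_beta_matrix(file.path(sp$qc, paste0(tis, "_betas_filtered.tsv")))
      apply_clock(clock, betas, sheet = sheet)
    })
    preds <- do.call(rbind, preds)
    write.table(preds, file.path(sp$predict, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    preds
  })

  # stage 4: mean-matching + GLAD
  glad <- run_stage("glad", {
    sheet <- read_sample_sheet(files[["sheet"]])
    preds <- read.delim(file.path(sp$predict, "predictions.tsv"),
                        stringsAsFactors = FALSE)
    g <- glad_table(preds, sheet,
                    scope = config$glad$scope %||% "pooled",
                    form = config$glad$form %||% "centered")
    write_glad_table(g, file.path(sp$glad, "glad.tsv"))
    g
  })

  # stage 5: comparison battery + diagnostic scatterplots
  report <- run_stage("compare", {
    sheet <- read_sample_sheet(files[["sheet"]])
    g <- read_glad_table(file.path(sp$glad, "glad.tsv"))
    preds <- read.delim(file.path(sp$predict, "predictions.tsv"),
                        stringsAsFactors = FALSE)
    rep <- run_comparisons(g, preds, sheet)
    write_comparison_report(rep, file.path(sp$compare, "report"))
    for (tis in c("sperm", "blood")) {
      sub <- g[g$tissue == tis, ]
      if (nrow(sub) > 0L) {
        pdf(file.path(sp$compare, paste0(tis, "_age_scatter.pdf")), 5, 5)
        plot(sub$age_years, sub$predicted_age,
             xlab = "chronological age (years)",
             ylab = "predicted epigenetic age (years)",
             main = paste0(tis, ": predicted vs chronological"),
             pch = ifelse(sub$group == "oligozoospermic", 17, 16))
        abline(0, 1, lty = 2)
        legend("topleft", pch = c(17, 16),
               legend = c("oligozoospermic", "normozoospermic"), bty = "n")
        dev.off()
      }
    }
    rep
  })

  # manifest: checksums of every persisted text table
  all_files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  all_files <- all_files[!grepl("manifest\\.json$", all_files)]
  manifest <- data.frame(
    file = sub(paste0("^", out_dir, "/?"), "", all_files),
    md5 = unname(tools::md5sum(all_files)),
    stringsAsFactors = FALSE)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  meta <- list(config_hash = md5_string(cfg_json),
               seed = config$seed,
               version = as.character(packageVersion("tsage")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               files = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(manifest = manifest, report = report)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(s), f)
  unname(tools::md5sum(f))
}

#' Analyze a cohort bundle in memory
#'
#' Lightweight in-memory equivalent of the file-based pipeline, used for
#' Monte-Carlo work: applies each tissue's true clock, builds the GLAD
#' table and runs the comparison battery. QC is optional (and off by
#' default) because simulated replicates are clean by construction.
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param scope,form passed to [glad_table()].
#' @param qc run [run_sample_qc()] on both matrices first.
#' @return list with `predictions`, `glad`, `report`.
#' @export
analyze_cohort <- function(bundle, scope = "pooled", form = "centered",
                           qc = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  sperm <- bundle$sperm_betas
  blood <- bundle$blood_betas
  if (qc) {
    sperm <- run_sample_qc(sperm, bundle$sheet, bundle$dlk1_ids,
                           bundle$intensity)$betas
    blood <- run_sample_qc(blood, bundle$sheet, bundle$dlk1_ids,
                           bundle$intensity)$betas
  }
  predictions <- rbind(
    apply_clock(bundle$true_sperm_clock, sperm, sheet = bundle$sheet),
    apply_clock(bundle$true_blood_clock, blood, sheet = bundle$sheet))
  glad <- glad_table(predictions, bundle$sheet, scope = scope, form = form)
  report <- run_comparisons(glad, predictions, bundle$sheet)
  list(predictions = predictions, glad = glad, report = report)
}

#' Monte-Carlo replicates of the simulated analysis
#'
#' Regenerates the cohort `n_replicates` times (varying only the seed),
#' analyzes each with [analyze_cohort()], and collects per-replicate
#' summaries: the sperm and blood between-group mean GLAD differences and
#' the battery's p-values.
#'
#' @param config a [sim_config()]; its seed is the base of the replicate
#'   seed stream.
#' @param n_replicates number of replicates.
#' @param seed base seed (default `config$seed`).
#' @return data.frame with one row per replicate: `replicate`, `seed`,
#'   `sperm_glad_diff`, `blood_glad_diff`, `p_sperm`, `p_blood`,
#'   `p_predicted_difference`.
#' @export
replicate_analysis <- function(config, n_replicates, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n_replicates <- assert_count(n_replicates, "n_replicates")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    res <- analyze_cohort(generate_cohort(cfg))
    gdiff <- function(tst) unname(tst$group_means[1] - tst$group_means[2])
    rep_ <- res$report
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed,
      sperm_glad_diff = gdiff(rep_$sperm_glad_test),
      blood_glad_diff = gdiff(rep_$blood_glad_test),
      p_sperm = rep_$sperm_glad_test$p_value,
      p_blood = rep_$blood_glad_test$p_value,
      p_predicted_difference = rep_$predicted_difference_test$p_value)
  }
  do.call(rbind, rows)
}

#' Detection power across acceleration levels
#'
#' For each sperm acceleration value in `accel_grid`, simulates
#' `n_replicates` cohorts and reports the fraction whose sperm GLAD test
#' rejects at level `alpha`, with the binomial Monte-Carlo standard error.
#'
#' @param config base [sim_config()] (its `sperm_accel_oligo` is swept).
#' @param accel_grid non-empty numeric vector of acceleration values.
#' @param n_replicates replicates per grid point (>= 50).
#' @param alpha rejection level (default 0.05).
#' @param seed base seed (default `config$seed`).
#' @return data.frame with `accel`, `power`, `mc_se`, `n_replicates`.
#' @export
power_analysis <- function(config, accel_grid, n_replicates = 200,
                           alpha = 0.05, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (length(accel_grid) == 0L) stop("accel_grid must be non-empty", call. = FALSE)
  if (n_replicates < 50) stop("n_replicates must be >= 50", call. = FALSE)
  rows <- lapply(seq_along(accel_grid), function(i) {
    cfg <- config
    cfg$sperm_accel_oligo <- accel_grid[i]
    sims <- replicate_analysis(cfg, n_replicates,
                               seed = derive_seed(seed, 100000L * i))
    pw <- mean(sims$p_sperm < alpha)
    data.frame(accel = accel_grid[i], power = pw,
               mc_se = sqrt(pw * (1 - pw) / n_replicates),
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}
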