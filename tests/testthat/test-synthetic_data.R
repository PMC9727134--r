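test_that("cohort bookkeeping: counts, pairing, truth coverage", {
  b <- generate_cohort(sim_config(seed = 1))
  expect_equal(length(unique(b$sheet$individual_id)), 34)
  expect_equal(nrow(b$sheet), 68)
  expect_equal(sum(b$sheet$tissue == "sperm"), 34)
  # one sperm + one blood per individual
  tab <- table(b$sheet$individual_id, b$sheet$tissue)
  expect_true(all(tab == 1))
  # matrix columns match the sheet's ids per tissue
  expect_setequal(colnames(b$sperm_betas),
                  b$sheet$sample_id[b$sheet$tissue == "sperm"])
  expect_setequal(colnames(b$blood_betas),
                  b$sheet$sample_id[b$sheet$tissue == "blood"])
  # truth covers every sample
  expect_setequal(b$truth$sample_id, b$sheet$sample_id)
  # within-individual ages agree across tissues
  expect_equal(b$sheet$age_years[match(paste0(unique(b$sheet$individual_id), "_sperm"), b$sheet$sample_id)],
               b$sheet$age_years[match(paste0(unique(b$sheet$individual_id), "_blood"), b$sheet$sample_id)])
})

test_that("same seed + config is byte-identical; different seed differs", {
  cfg <- light_config(seed = 42, sperm_accel_oligo = 0.05)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
  b3 <- generate_cohort(light_config(seed = 43, sperm_accel_oligo = 0.05))
  expect_false(identical(b1$sperm_betas, b3$sperm_betas))
  # the generator restores the caller's RNG state
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_cohort(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("all emitted betas lie in [0,1] across seeds and configs", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_background_cpgs = 500,
                      sperm_accel_oligo = 0.15,
                      contamination_fraction = c(0, 0.3, 0.6, 0, 0.9)[seed])
    b <- generate_cohort(cfg)
    expect_true(all(b$sperm_betas >= 0 & b$sperm_betas <= 1))
    expect_true(all(b$blood_betas >= 0 & b$blood_betas <= 1))
    expect_true(all(b$sheet$age_years >= 18 & b$sheet$age_years <= 60))
  }
})

test_that("noise-free zero-acceleration cohort inverts exactly through its true clocks", {
  b <- generate_cohort(sim_config(seed = 3, beta_noise_sd = 0))
  for (tis in c("sperm", "blood")) {
    clock <- if (tis == "sperm") b$true_sperm_clock else b$true_blood_clock
    betas <- if (tis == "sperm") b$sperm_betas else b$blood_betas
    pred <- apply_clock(clock, betas)
    chron <- b$sheet$age_years[match(pred$sample_id, b$sheet$sample_id)]
    expect_equal(pred$predicted_age_years, chron, tolerance = 1e-10)
  }
})

test_that("with acceleration, noise-free predictions equal effective ages", {
  b <- generate_cohort(sim_config(seed = 4, beta_noise_sd = 0,
                                  sperm_accel_oligo = 0.095))
  pred <- apply_clock(b$true_sperm_clock, b$sperm_betas)
  eff <- b$truth$effective_age[match(pred$sample_id, b$truth$sample_id)]
  expect_equal(pred$predicted_age_years, eff, tolerance = 1e-8)
  oligo <- b$sheet$group[match(pred$sample_id, b$sheet$sample_id)] == "oligozoospermic"
  chron <- b$sheet$age_years[match(pred$sample_id, b$sheet$sample_id)]
  expect_equal(eff[oligo], chron[oligo] * 1.095)
  expect_equal(eff[!oligo], chron[!oligo])
})

test_that("background CpG mass respects the bimodal valley bound", {
  b <- generate_cohort(sim_config(seed = 5, n_background_cpgs = 3000))
  bg <- b$sperm_betas[grep("^cgX", rownames(b$sperm_betas)), ]
  f_mid <- mean(bg > 0.2 & bg < 0.8)
  expect_lte(f_mid, 0.2)
  expect_gte(mean(bg <= 0.2), 0.25)
  expect_gte(mean(bg >= 0.8), 0.25)
})

test_that("mix_contamination is the stated convex combination", {
  sp <- c(cg1 = 0.1, cg2 = 0.0, cg3 = 0.9)
  bl <- c(cg3 = 0.5, cg1 = 0.3, cg2 = 1.0)  # shuffled names
  expect_identical(mix_contamination(sp, bl, 0), sp)
  expect_equal(unname(mix_contamination(sp, bl, 1)), unname(bl[names(sp)]))
  half <- mix_contamination(sp, bl, 0.5)
  expect_equal(unname(half), c(0.2, 0.5, 0.7))
  expect_error(mix_contamination(sp, c(cgZ = 0.2, cg1 = 0.1, cg2 = 0.3), 0.5),
               "mismatched CpG")
  expect_error(mix_contamination(1:3 / 10, 1:4 / 10, 0.5), "equal length")
  expect_error(mix_contamination(sp, bl, 1.2), "fraction")
})

test_that("DLK1 mean beta is affine in contamination fraction", {
  # noise-free so the affine relation is exact
  base <- sim_config(seed = 6, beta_noise_sd = 0, background_noise_sd = 0,
                     n_background_cpgs = 1, n_dlk1_cpgs = 4)
  fracs <- c(0, 0.25, 0.5, 1)
  means <- sapply(fracs, function(f) {
    cfg <- base; cfg$contamination_fraction <- f
    b <- generate_cohort(cfg)
    mean(b$sperm_betas[b$dlk1_ids, ])
  })
  # slope = blood mean - sperm mean = 0.80 - 0.05
  expect_equal(means, 0.05 + fracs * (0.80 - 0.05), tolerance = 1e-12)
})

test_that("build_true_clock is the algebraic inverse of the generative map", {
  # single CpG: beta = 0.2 + 0.005 * age  =>  age = 200 * beta - 40
  clock <- build_true_clock(0.2, 0.005, "cg001")
  expect_equal(unname(clock$coefficients), 200)
  expect_equal(clock$intercept, -40)
  m <- matrix(0.35, 1, 1, dimnames = list("cg001", "s1"))
  expect_equal(apply_clock(clock, m)$predicted_age_years, 30)

  # several CpGs, exact inversion at a grid of ages
  set.seed(11)
  k <- 8
  b0 <- runif(k, 0.2, 0.3); s <- runif(k, 0.003, 0.006)
  ids <- sprintf("cg%03d", 1:k)
  clock <- build_true_clock(b0, s, ids)
  ages <- c(20, 30, 40)
  betas <- sapply(ages, function(a) b0 + s * a)
  dimnames(betas) <- list(ids, paste0("s", ages))
  expect_equal(apply_clock(clock, betas)$predicted_age_years, ages,
               tolerance = 1e-10)

  expect_error(build_true_clock(c(0.2, 0.3), c(0.005, 0), c("a", "b")),
               "degenerate")
  expect_error(build_true_clock(0.2, 0.005, c("a", "b")), "equal positive length")
})

test_that("true-clock prediction error SD shrinks as 1/sqrt(k)", {
  # Monte-Carlo: fixed noise, k = 10 vs 40 CpGs -> error-SD ratio ~ 2
  err_sd <- function(k, reps = 200) {
    set.seed(123)
    b0 <- runif(k, 0.2, 0.3); s <- runif(k, 0.004, 0.006)
    ids <- sprintf("cg%04d", 1:k)
    clock <- build_true_clock(b0, s, ids)
    errs <- replicate(reps, {
      betas <- matrix(b0 + s * 35 + rnorm(k, 0, 0.05), ncol = 1,
                      dimnames = list(ids, "s1"))
      apply_clock(clock, betas)$predicted_age_years - 35
    })
    sd(errs)
  }
  ratio <- err_sd(10) / err_sd(40)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("saturating slope/baseline ranges are rejected as unusable", {
  cfg <- sim_config(seed = 1, slope_range = c(0.02, 0.03),
                    baseline_low = c(0.15, 0.35), baseline_high = c(0.65, 0.85))
  expect_error(generate_cohort(cfg), "unusable generative regime")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_oligo = 0), "n_oligo")
  expect_error(sim_config(beta_noise_sd = -0.1), "beta_noise_sd")
  expect_error(sim_config(contamination_fraction = 1.5), "contamination_fraction")
  expect_error(sim_config(sperm_accel_oligo = -1), "sperm_accel_oligo")
})

test_that("mean oligo sperm GLAD increases with injected acceleration", {
  # Monte-Carlo ordering over 3 acceleration levels
  mean_diff <- function(accel) {
    sims <- replicate_analysis(light_config(sperm_accel_oligo = accel), 40,
                               seed = 2024)
    mean(sims$sperm_glad_diff)
  }
  d <- vapply(c(0, 0.05, 0.15), mean_diff, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("write_cohort round-trips through the plain-text formats", {
  dir <- tempfile()
  b <- generate_cohort(light_config(seed = 8, n_background_cpgs = 20))
  paths <- write_cohort(b, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_beta_matrix(paths["sperm_betas"]), b$sperm_betas,
               tolerance = 1e-12)
  sheet2 <- read_sample_sheet(paths["sheet"])
  expect_equal(sheet2$sample_id, b$sheet$sample_id)
  expect_equal(sheet2$age_years, b$sheet$age_years, tolerance = 1e-12)
  clock2 <- load_clock(paths["sperm_clock"])
  expect_equal(clock2$coefficients, b$true_sperm_clock$coefficients,
               tolerance = 1e-12)
  meta <- jsonlite::read_json(paths["meta"], simplifyVector = TRUE)
  expect_equal(meta$seed, b$config$seed)
  expect_setequal(meta$truth$sample_id, b$sheet$sample_id)
  unlink(dir, recursive = TRUE)
})
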