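# shared fixtures and independent oracles

# small cohort config for Monte-Carlo loops: background/DLK1 CpGs trimmed
# because they carry no age signal (QC-specific tests use full configs)
light_config <- function(...) {
  args <- utils::modifyList(list(n_background_cpgs = 1, n_dlk1_cpgs = 1),
                            list(...))
  do.call(sim_config, args)
}

# independent Welch oracle: stats::t.test
oracle_welch <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# independent OLS oracle: stats::lm + summary
oracle_ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, adj_r2 = s$adj.r.squared,
       p = unname(s$coefficients[2, 4]))
}

# tiny clock fixture written to a temp CSV
write_clock_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("cpg_id,coefficient", rows), path)
  path
}
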