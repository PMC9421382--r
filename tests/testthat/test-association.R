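make_sheet <- function(n, epds, sex = "female", seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             epds = epds, fetal_sex = rep_len(sex, n),
             chip = "chip1", chip_position = sprintf("R%02d", rep(1:4, length.out = n)),
             extraction_method = "kitA",
             bisulfite_concentration = round(rnorm(n, 50, 5), 1),
             group = "A", stringsAsFactors = FALSE)
}

test_that("per-CpG regression matches the normal-equations oracle to 1e-10", {
  set.seed(17)
  n <- 30; p <- 5
  epds <- round(pmin(pmax(rnorm(n, 7, 4.4), 0), 30))
  cov1 <- rnorm(n); cov2 <- rnorm(n)
  beta <- rand_beta(p, n, seed = 18)
  sheet <- make_sheet(n, epds)
  colnames(beta) <- sheet$sample_id
  fit <- fit_cpg_regressions(beta, sheet,
                             covariates = cbind(cov1 = cov1, cov2 = cov2),
                             stratum = "female")
  X <- cbind(1, epds, cov1, cov2)
  for (i in seq_len(p)) {
    o <- oracle_ols(X, beta[i, ])
    expect_equal(fit$slope[i], unname(o$slope), tolerance = 1e-10)
    expect_equal(fit$se[i], unname(o$se), tolerance = 1e-10)
    expect_equal(fit$p[i], unname(o$p), tolerance = 1e-10)
  }
  expect_equal(fit$df, rep(n - 4L, p))
  expect_equal(fit$n_used, rep(n, p))
})

test_that("perfect fits floor the p-value and constants go degenerate", {
  n <- 20
  epds <- rep(c(2, 5, 9, 14), 5)
  sheet <- make_sheet(n, epds)
  beta <- rbind(exact = 0.3 + 0.01 * epds, flat = rep(0.4, n))
  colnames(beta) <- sheet$sample_id
  fit <- fit_cpg_regressions(beta, sheet)
  expect_equal(fit$slope[1], 0.01, tolerance = 1e-12)
  expect_lte(fit$p[1], 1e-300)
  expect_equal(fit$status[2], "degenerate")
  expect_true(is.na(fit$p[2]))
})

test_that("stratification, listwise deletion and error paths behave", {
  n <- 40
  epds <- round(runif(n, 0, 30))
  sheet <- make_sheet(n, epds, sex = rep(c("female", "male"), each = n / 2))
  sheet$epds[3] <- NA
  beta <- rand_beta(4, n, seed = 3)
  colnames(beta) <- sheet$sample_id
  fit_f <- fit_cpg_regressions(beta, sheet, stratum = "female")
  expect_equal(unique(fit_f$n_used), n / 2 - 1L)     # one NA dropped
  expect_equal(attr(fit_f, "n_dropped"), 1L)
  # female-only fit ignores male samples entirely
  o <- oracle_ols(cbind(1, epds[sheet$fetal_sex == "female" & !is.na(sheet$epds)]),
                  beta[1, sheet$fetal_sex == "female" & !is.na(sheet$epds)])
  expect_equal(fit_f$slope[1], unname(o$slope), tolerance = 1e-10)

  sheet_m <- sheet; sheet_m$fetal_sex <- "female"
  expect_error(fit_cpg_regressions(beta, sheet_m, stratum = "male"),
               "empty stratum")
  sheet_na <- sheet; sheet_na$epds <- NA
  expect_error(fit_cpg_regressions(beta, sheet_na, stratum = "female"),
               "EPDS")
  # categorical covariates expand to treatment contrasts
  fit_c <- fit_cpg_regressions(beta, sheet, covariates = "chip_position",
                               stratum = "female")
  expect_equal(unique(fit_c$df), (n / 2 - 1L) - 5L)  # intercept+epds+3 dummies
})

test_that("one-sided KS statistic and tails match the stated forms", {
  r <- ks_uniformity_test(c(0.25, 0.5, 0.75), exact = FALSE)
  expect_equal(r$d_plus, 0.25)
  expect_equal(r$p, exp(-2 * 3 * 0.25^2))
  # exact small-n tail agrees with the independent reference implementation
  re <- ks_uniformity_test(c(0.25, 0.5, 0.75))
  expect_equal(re$method, "exact")
  expect_equal(re$p, 0.609375, tolerance = 1e-12)
  set.seed(6)
  x <- runif(50)
  expect_equal(ks_uniformity_test(x)$p,
               ks.test(x, "punif", alternative = "greater")$p.value,
               tolerance = 1e-9)
  # no low-end excess
  r1 <- ks_uniformity_test(rep(1, 10))
  expect_equal(r1$d_plus, 0)
  expect_equal(r1$p, 1)
  expect_error(ks_uniformity_test(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(ks_uniformity_test(numeric(0)), "nonempty")
})

test_that("EPDS-vCpG selection is strict, skips degenerates, and is calibrated", {
  tab <- data.frame(probe_id = c("a", "b", "c"),
                    p = c(0.005, 0.0049, NA),
                    status = c("ok", "ok", "degenerate"))
  expect_identical(select_epds_vcpgs(tab, 0.005), "b")
  empty <- tab[0, ]
  expect_length(select_epds_vcpgs(empty, 0.005), 0)

  set.seed(8)
  unif <- data.frame(probe_id = sprintf("cg%04d", 1:1000),
                     p = runif(1000), status = "ok")
  k <- length(select_epds_vcpgs(unif, 0.005))
  expect_lt(abs(k - 5), 3 * sqrt(1000 * 0.005 * 0.995))
})

test_that("probe-set intersection and count summaries do the arithmetic", {
  expect_identical(intersect_probe_sets(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_length(intersect_probe_sets("x", "y"), 0)
  expect_identical(intersect_probe_sets(c("b", "a"), c("a", "b")), c("a", "b"))

  s <- summarize_counts(4716, 422691, 1825)
  expect_equal(s$percent, 1.1)
  expect_equal(s$fold_ratio, 2.6)
  expect_equal(summarize_counts(letters[1:5], letters[1:5])$percent, 100.0)
  expect_error(summarize_counts(0, 0), "empty universe")
  expect_true(is.na(summarize_counts(10, 100, character(0))$fold_ratio))
  expect_error(summarize_counts(c("a", "z"), c("a", "b")), "subset")
})
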