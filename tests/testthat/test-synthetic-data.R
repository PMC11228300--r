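test_that("default cohort has the study's group sizes and region count", {
  ont <- shipped_ontology()
  coh <- generate_cohort(cohort_spec(ont, seed = 3))
  expect_equal(dim(coh$counts), c(11, 196))
  expect_equal(as.vector(table(coh$genotype)), c(6, 5))
  expect_true(all(coh$counts >= 0))
  expect_true(is.integer(coh$counts))
})

test_that("identical specs generate bit-identical cohorts", {
  ont <- toy_ontology(10)
  spec <- cohort_spec(ont, c(WT = 4, KO = 4), seed = 11,
                      correlation_blocks = list(
                        list(genotype = "WT", regions = paste0("R", 1:3),
                             rho = 0.8)))
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$latent_density, b$latent_density)
})

test_that("zero dispersion and no blocks give constant region columns", {
  ont <- toy_ontology(4, volumes = c(1, 2, 0.5, 1))
  coh <- generate_cohort(cohort_spec(ont, c(A = 5), dispersion = 0,
                                     baseline_log_mean = log(100),
                                     seed = 1))
  expect_true(all(apply(coh$counts, 2, function(v) length(unique(v))) == 1))
  expect_equal(unname(coh$counts[1, ]),
               as.integer(round(100 * ont$volume_mm3)))
})

test_that("planted blocks reproduce the target rank correlation", {
  # Monte-Carlo over 200 seeds: a 5-region block planted at rho* = 0.95
  # with n = 40 animals must recover mean pairwise Spearman >= 0.8
  ont <- toy_ontology(5)
  mean_rhos <- vapply(1:200, function(s) {
    spec <- cohort_spec(ont, c(A = 40), seed = s,
                        correlation_blocks = list(
                          list(genotype = "A", regions = paste0("R", 1:5),
                               rho = 0.95)))
    d <- compute_density(generate_cohort(spec))
    r <- cor(d$values, method = "spearman")
    mean(r[upper.tri(r)])
  }, numeric(1))
  expect_gte(mean(mean_rhos), 0.8)
  # and the copula calibration is tight: mean close to the target itself
  expect_equal(mean(mean_rhos), 0.95, tolerance = 0.02)
})

test_that("marginal contract: mean density matches the log-normal mean", {
  ont <- toy_ontology(4, volumes = rep(1, 4))
  spec <- cohort_spec(ont, c(A = 800), baseline_log_mean = log(100),
                      dispersion = 0.5, seed = 5)
  d <- compute_density(generate_cohort(spec))
  expected <- 100 * exp(0.5^2 / 2)
  expect_equal(mean(colMeans(d$values)), expected, tolerance = 0.05)
})

test_that("impossible correlation structures fail loudly", {
  ont <- toy_ontology(4)
  spec <- cohort_spec(ont, c(A = 4), seed = 1, correlation_blocks = list(
    list(genotype = "A", regions = c("R1", "R2", "R3"), rho = 0.95),
    list(genotype = "A", regions = c("R1", "R4"), rho = -0.9)))
  # R2,R3 ~ R1 at ~0.97 latent while R4 is at -0.93 with R1 only: not PD
  expect_error(generate_cohort(spec), "positive definite")
  expect_error(cohort_spec(ont, c(A = 2)), "at least 3")
  expect_error(cohort_spec(ont, c(A = 4), correlation_blocks = list(
    list(genotype = "A", regions = c("R1", "R2"), rho = 1))), "rho")
})

test_that("counts round-trip through the TSV dialect", {
  ont <- toy_ontology(6)
  coh <- generate_cohort(cohort_spec(ont, c(WT = 3, KO = 3), seed = 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(coh, tmp)
  back <- read_counts_table(tmp, ont)
  expect_identical(back$counts, coh$counts)
  expect_equal(as.character(back$genotype), as.character(coh$genotype))
})

test_that("trial traces honour their occupancy profile on average", {
  frac <- vapply(1:50, function(s) {
    tr <- generate_trial_trace(600, c(A = 0.3, B = 0.2), seed = s)
    sm <- summarize_trial(tr)
    c(sm$zone_time[["A"]], sm$zone_time[["B"]]) / 600
  }, numeric(2))
  expect_equal(mean(frac[1, ]), 0.3, tolerance = 0.05 / 0.3)
  expect_equal(mean(frac[2, ]), 0.2, tolerance = 0.05 / 0.2)
})

test_that("trace event streams are well-formed and bounded", {
  for (s in 1:20) {
    tr <- generate_trial_trace(300, c(mouse = 0.4, object = 0.2), seed = s)
    expect_true(all(diff(tr$t_s) > 0))
    expect_true(all(tr$t_s >= 0 & tr$t_s < 300))
    if (nrow(tr) > 1)
      expect_true(all(tr$zone[-1] != tr$zone[-nrow(tr)]))
  }
  one <- generate_trial_trace(300, c(A = 1), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(summarize_trial(one)$zone_time[["A"]], 300)
  expect_error(generate_trial_trace(300, c(A = -0.1)), "non-negative")
  expect_error(generate_trial_trace(300, c(A = 0.7, B = 0.5)), "<= 1")
})
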