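test_that("published pg values convert to the published Mbp values", {
  pg <- c(0.5533, 0.4395, 0.7865, 0.7860)
  mbp <- round(convert_units(pg, from = "pg"), 1)
  expect_identical(mbp, c(541.1, 429.8, 769.2, 768.7))
  # round trip is the identity to 6 significant figures
  back <- convert_units(convert_units(1.0, from = "pg"), from = "mbp")
  expect_equal(back, 1.0, tolerance = 1e-6)
  expect_equal(convert_units(978, from = "mbp"), 1.0)
  expect_error(convert_units(-1, from = "pg"))
})

test_that("ratio-based 1C estimation follows the internal-standard formula", {
  expect_equal(estimate_1c(100, 100)$c1_mbp, 328)
  expect_equal(estimate_1c(200, 100)$c1_mbp, 656)
  # the published S. oryzae female value back-computes from its ratio
  est <- estimate_1c(769.2 / 328 * 50, 50)
  expect_equal(est$c1_mbp, 769.2, tolerance = 1e-9)
  expect_equal(round(est$c1_pg, 4), 0.7865)
  expect_error(estimate_1c(0, 100), "positive")
})

test_that("KDE peak finding recovers two Gaussian populations", {
  set.seed(10)
  run <- data.frame(fluorescence = c(rnorm(5000, 100, 2),
                                     rnorm(5000, 234, 234 * 0.02)))
  pk <- locate_2c_peaks(run, n_peaks = 2)
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$mean_fluorescence[1] - 100) / 100, 0.01)
  expect_lt(abs(pk$mean_fluorescence[2] - 234) / 234, 0.01)
  expect_true(all(diff(pk$mean_fluorescence) > 0))

  one <- locate_2c_peaks(run$fluorescence[1:5000], n_peaks = 1)
  expect_lt(abs(one$mean_fluorescence - 100) / 100, 0.005)
})

test_that("featureless input raises an unresolved-peaks error", {
  set.seed(11)
  noise <- data.frame(fluorescence = runif(2000, 10, 500))
  expect_error(locate_2c_peaks(noise, n_peaks = 2), "unresolved peaks")
  expect_error(locate_2c_peaks(1:50), "100 events")
})

test_that("group summaries give mean, SE and n", {
  df <- tibble::tibble(species = "x", sex = "f", c1_mbp = c(540, 542))
  s <- summarize_group(df, species, sex)
  expect_equal(s$mean_mbp, 541)
  expect_equal(s$se_mbp, 1)
  expect_identical(s$n, 2L)

  single <- summarize_group(tibble::tibble(c1_mbp = 540))
  expect_true(is.na(single$se_mbp))
  expect_error(summarize_group(tibble::tibble(c1_mbp = numeric(0))))
})

test_that("B-carrier partitioning splits only at credible gaps", {
  # two clusters at the published male S. zeamais scale
  set.seed(12)
  v <- c(rnorm(3, 709.2, 2), rnorm(2, 768.7, 2))
  p <- partition_b_carriers(v)
  expect_setequal(unique(p$b_group), c("without_B", "with_B"))
  expect_identical(sum(p$b_group == "with_B"), 2L)

  # homogeneous values stay together
  set.seed(13)
  same <- rnorm(6, 700, 3)
  expect_identical(unique(partition_b_carriers(same)$b_group), "all")

  # two values with a huge gap become two singleton groups
  two <- partition_b_carriers(c(700, 769))
  expect_identical(two$b_group, c("without_B", "with_B"))

  expect_error(partition_b_carriers(700), "at least 2")
})

test_that("estimates are invariant to instrument gain", {
  cfg <- simulation_config(seed = 20, nuclei_per_population = 2000)
  run <- simulate_flow_run(cfg, "Sitophilus_granarius")
  est1 <- flow_genome_size(run, standard_is = "lower")
  run2 <- run
  run2$fluorescence <- run2$fluorescence * 7.3
  est2 <- flow_genome_size(run2, standard_is = "lower")
  expect_equal(est1$c1_mbp, est2$c1_mbp, tolerance = 1e-9)
})

test_that("the blind pipeline recovers a known genome size", {
  cfg <- simulation_config(seed = 21)
  run <- simulate_flow_run(cfg, "Sitophilus_granarius")  # truth 541.1 Mbp
  est <- flow_genome_size(run, standard_is = "lower")
  expect_lt(abs(est$c1_mbp - 541.1) / 541.1, 0.01)
  expect_identical(est$species, "Sitophilus_granarius")

  # degenerate noise: CV 0 recovers the truth to rounding
  cfg0 <- simulation_config(seed = 22, cv = 0, nuclei_per_population = 1000)
  run0 <- simulate_flow_run(cfg0, "Sitophilus_linearis")  # truth 429.8
  est0 <- flow_genome_size(run0, standard_is = "lower")
  expect_equal(est0$c1_mbp, 429.8, tolerance = 1e-6)
})

test_that("report table mirrors the publication layout", {
  cfg <- simulation_config(seed = 23, nuclei_per_population = 1500)
  ests <- purrr::map_dfr(1:3, function(i) {
    c2 <- cfg; c2$seed <- cfg$seed + i
    flow_genome_size(simulate_flow_run(c2, "Sitophilus_granarius",
                                       individual = paste0("f", i)),
                     standard_is = "lower")
  })
  rep <- genome_size_report(ests)
  expect_identical(rep$n, 3L)
  expect_match(rep$pg_se, "^0\\.5\\d{3} ± 0\\.\\d{4}$")
  expect_match(rep$mbp_se, "^5\\d{2}\\.\\d ± ")
})
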