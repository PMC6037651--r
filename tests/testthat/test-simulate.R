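test_that("character simulation respects its degenerate limits", {
  cfg0 <- simulation_config(seed = 1, change_prob = 0)
  m0 <- simulate_characters(cfg0)
  expect_true(all(m0$states == 0L))

  cfg1 <- simulation_config(seed = 1, missing_fraction = 1)
  m1 <- simulate_characters(cfg1)
  expect_true(all(is.na(m1$states)))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(seed = 9, change_prob = 0.2,
                           missing_fraction = 0.1)
  expect_identical(simulate_characters(cfg)$states,
                   simulate_characters(cfg)$states)
  expect_identical(simulate_flow_run(cfg, "Sitophilus_oryzae"),
                   simulate_flow_run(cfg, "Sitophilus_oryzae"))
  expect_identical(as.data.frame(simulate_karyotypes(cfg)),
                   as.data.frame(simulate_karyotypes(cfg)))
  cfg2 <- simulation_config(seed = 10, change_prob = 0.2)
  expect_false(identical(simulate_characters(cfg)$states,
                         simulate_characters(cfg2)$states))
})

test_that("states and flags reflect the configured evolution model", {
  cfg <- simulation_config(seed = 2, n_characters = 200, change_prob = 0.3,
                           ordered_fraction = 0.25)
  m <- simulate_characters(cfg)
  expect_identical(sum(m$ordered), 50L)
  expect_true(all(m$states >= 0L & m$states <= 8L))
  # unordered characters never leave the 0..4 state alphabet
  expect_lte(max(m$states[, !m$ordered]), 4L)
  # with a high change rate most characters vary
  expect_gt(mean(apply(m$states, 2, function(s) length(unique(s)) > 1)), 0.5)
})

test_that("per-edge change frequency matches the configured probability", {
  # two taxa joined at the root: each leaf state is one edge draw from the
  # root state, so the per-character change frequency estimates change_prob
  cfg <- simulation_config(
    seed = 4, tree = ape::read.tree(text = "(a,b);"),
    n_characters = 4000, change_prob = 0.1, ordered_fraction = 1
  )
  m <- simulate_characters(cfg)
  phat <- mean(m$states != 0L)
  expect_lt(abs(phat - 0.1), 3 * sqrt(0.1 * 0.9 / 8000))
})

test_that("low-homoplasy characters let parsimony recover the true tree", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- simulation_config(seed = seed, n_characters = 200,
                             change_prob = 0.05)
    m <- simulate_characters(cfg)
    res <- mp_search(m)
    nw <- vapply(
      mp_trees(res),
      function(t) ape::write.tree(
        root_with_outgroup(t, "Otiorhynchus_bisulcatus")), "")
    truth <- ape::read.tree(
      text = "(Otiorhynchus_bisulcatus,((Sitophilus_zeamais,Sitophilus_oryzae),(Sitophilus_granarius,Sitophilus_linearis)));")
    ok <- length(nw) == 1 &&
      same_topology(root_with_outgroup(mp_trees(res)[[1]],
                                       "Otiorhynchus_bisulcatus"), truth)
    hits <- hits + ok
  }
  expect_gte(hits, 8L)
})

test_that("simulated karyotypes are valid and cover the encoder's categories", {
  for (seed in c(3, 14, 15)) {
    recs <- simulate_karyotypes(simulation_config(seed = seed), n = 5)
    expect_true(all(validate_karyotype(recs)$valid))
    expect_setequal(unique(recs$diploid_number), c(22L, 24L))
    expect_true(any(recs$b_max > 0))
    expect_true(any(recs$sex_system == "neo-XY"))
    expect_true(any(recs$auto_subtelocentric + recs$auto_telocentric > 0))
  }
})

test_that("a simulated B-carrier load is detected by the gap partition", {
  cfg <- simulation_config(seed = 6, nuclei_per_population = 2000)
  base <- 709.2
  ests <- purrr::map_dfr(1:5, function(i) {
    c2 <- cfg
    c2$seed <- cfg$seed + i
    truth <- if (i <= 3) base else base + 59.5  # B carriers
    flow_genome_size(
      simulate_flow_run(c2, "Sitophilus_zeamais", sex = "male",
                        individual = paste0("m", i), true_1c_mbp = truth),
      standard_is = "lower")
  })
  p <- partition_b_carriers(ests)
  expect_identical(p$b_group, c(rep("without_B", 3), rep("with_B", 2)))
})
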