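#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. The defaults
#' mirror the scale of the weevil study: five taxa related as in the
#' reference topology, 20 discrete characters, two co-prepared fluorescence
#' populations of 5,000 nuclei each with 2% CV against a 328-Mbp internal
#' standard, and the four species' 1C truths set to the published female
#' estimates.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param tree Rooted binary `phylo` the characters evolve on.
#' @param n_characters Number of characters to simulate.
#' @param change_prob Per-edge probability of a state change.
#' @param ordered_fraction Fraction of characters evolving on an ordered
#'   ladder (+1 per change) rather than jumping to a random other state.
#' @param missing_fraction Fraction of leaf states masked to missing.
#' @param nuclei_per_population Nuclei per fluorescence population.
#' @param cv Coefficient of variation of each fluorescence population, in
#'   percent.
#' @param gain Instrument gain, fluorescence units per Mbp.
#' @param true_1c_mbp Named vector of true 1C sizes (Mbp) per species.
#' @param standard_1c_mbp 1C of the internal standard (Mbp).
#' @param debris_fraction Optional fraction of uniform debris events added
#'   to stress peak finding.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              tree = ape::read.tree(text = paste0(
                                "(Otiorhynchus_bisulcatus,",
                                "((Sitophilus_zeamais,Sitophilus_oryzae),",
                                "(Sitophilus_granarius,Sitophilus_linearis)));")),
                              n_characters = 20,
                              change_prob = 0.05,
                              ordered_fraction = 0.2,
                              missing_fraction = 0,
                              nuclei_per_population = 5000,
                              cv = 2,
                              gain = 0.1,
                              true_1c_mbp = c(
                                Sitophilus_granarius = 541.1,
                                Sitophilus_linearis = 429.8,
                                Sitophilus_oryzae = 769.2,
                                Sitophilus_zeamais = 713.5),
                              standard_1c_mbp = 328,
                              debris_fraction = 0) {
  stopifnot(
    inherits(tree, "phylo"),
    n_characters >= 1, nuclei_per_population >= 1,
    change_prob >= 0, change_prob <= 1,
    ordered_fraction >= 0, ordered_fraction <= 1,
    missing_fraction >= 0, missing_fraction <= 1,
    cv >= 0, gain > 0, debris_fraction >= 0, debris_fraction < 1
  )
  structure(
    list(seed = as.integer(seed), tree = tree,
         n_characters = as.integer(n_characters),
         change_prob = change_prob, ordered_fraction = ordered_fraction,
         missing_fraction = missing_fraction,
         nuclei_per_population = as.integer(nuclei_per_population),
         cv = cv, gain = gain, true_1c_mbp = true_1c_mbp,
         standard_1c_mbp = standard_1c_mbp,
         debris_fraction = debris_fraction),
    class = "sim_config"
  )
}

#' Simulate discrete characters on a known tree
#'
#' Each character evolves independently from root state 0 down the rooted
#' tree; on every edge the state changes with probability `change_prob` —
#' by +1 for ordered-ladder characters, or to a uniformly drawn different
#' state (0..4) for unordered ones. Characters model rare discrete
#' rearrangement events, not a reversible substitution process. A
#' `missing_fraction` of leaf states is masked afterwards.
#'
#' @param config A [simulation_config()].
#' @return A [char_matrix] over the tree's tips with known generating tree.
#' @examples
#' m <- simulate_characters(simulation_config(seed = 42))
#' glance(m)
#' @export
simulate_characters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  nch <- config$n_characters
  n_ord <- round(config$ordered_fraction * nch)
  ordered <- c(rep(TRUE, n_ord), rep(FALSE, nch - n_ord))

  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  states <- matrix(0L, nrow = nnode, ncol = nch)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chl <- tree$edge[e, 2]
    s <- states[par, ]
    chg <- stats::runif(nch) < config$change_prob
    if (any(chg & ordered)) {
      i <- chg & ordered
      s[i] <- s[i] + 1L
    }
    if (any(chg & !ordered)) {
      i <- which(chg & !ordered)
      new <- vapply(s[i], function(cur) {
        pool <- setdiff(0:4, cur)
        pool[sample.int(length(pool), 1)]
      }, 1L)
      s[i] <- new
    }
    states[chl, ] <- s
  }
  leaf <- states[seq_len(ntip), , drop = FALSE]
  rownames(leaf) <- tree$tip.label
  colnames(leaf) <- sprintf("sim_char_%02d", seq_len(nch))
  if (config$missing_fraction > 0) {
    mask <- stats::runif(length(leaf)) < config$missing_fraction
    leaf[mask] <- NA_integer_
  }
  char_matrix(leaf, ordered = ordered)
}

#' Simulate a blind two-population flow-cytometry run
#'
#' Emulates one co-preparation of a sample individual with the internal
#' standard: two Gaussian 2C populations, means `gain * 2 * 1C`, with the
#' configured CV and equal nuclei counts; events are shuffled and unlabeled
#' (estimation is blind). Optionally adds uniform debris events.
#'
#' @param config A [simulation_config()].
#' @param species Species name (must be in `config$true_1c_mbp`).
#' @param sex `"female"` or `"male"`.
#' @param individual Individual identifier carried into the run.
#' @param true_1c_mbp Override of the species' true 1C (e.g. to add a
#'   B-chromosome load); default from config.
#' @return A tibble with columns `fluorescence`, `species`, `sex`,
#'   `individual`.
#' @export
simulate_flow_run <- function(config, species, sex = "female",
                              individual = "ind1", true_1c_mbp = NULL) {
  stopifnot(inherits(config, "sim_config"))
  true_1c <- true_1c_mbp %||% config$true_1c_mbp[[species]]
  if (is.null(true_1c)) stop("no true 1C configured for ", species)
  set.seed(config$seed)
  n <- config$nuclei_per_population
  m_samp <- config$gain * 2 * true_1c
  m_std <- config$gain * 2 * config$standard_1c_mbp
  sd_of <- function(m) config$cv / 100 * m
  ev <- c(stats::rnorm(n, m_samp, sd_of(m_samp)),
          stats::rnorm(n, m_std, sd_of(m_std)))
  if (config$debris_fraction > 0) {
    nd <- round(config$debris_fraction * length(ev) /
                  (1 - config$debris_fraction))
    ev <- c(ev, stats::runif(nd, min(ev) * 0.2, max(ev) * 1.2))
  }
  ev <- pmax(ev, .Machine$double.eps)
  ev <- ev[sample.int(length(ev))]
  tibble::tibble(fluorescence = ev, species = species, sex = sex,
                 individual = individual)
}

#' Simulate random valid karyotype records
#'
#' Draws `n` structurally valid records that, across the set, exercise every
#' encoder category: both diploid numbers, B-chromosome presence, both sex
#' systems, a telocentric-range element, and varied X/Y morphologies and
#' pattern codes.
#'
#' @param config A [simulation_config()] (only the seed is used).
#' @param n Number of records (>= 2).
#' @return A `karyotype_tbl` tibble; all rows pass [validate_karyotype()].
#' @export
simulate_karyotypes <- function(config, n = 5) {
  stopifnot(inherits(config, "sim_config"), n >= 2)
  set.seed(config$seed)
  recs <- purrr::map_dfr(seq_len(n), function(i) {
    # forced coverage on the first four records, random beyond
    dn <- if (i == 1) 22L else if (i == 2) 24L else sample(c(22L, 24L), 1)
    n_auto <- dn - 2L
    n_sub <- sample(0:(n_auto / 2), 1) * 2L
    n_telo <- if (i == 3) 2L else 0L
    n_meta <- n_auto - n_sub - n_telo
    if (n_meta < 0) { n_sub <- n_sub + n_meta; n_meta <- 0L }
    karyotype_records(
      species = sprintf("sim_taxon_%02d", i),
      diploid_number = dn,
      auto_metacentric = n_meta,
      auto_submetacentric = n_sub,
      auto_subtelocentric = n_telo,
      x_class = sample(c("metacentric", "submetacentric"), 1),
      y_class = sample(c("metacentric", "dot-like", "subtelocentric"), 1),
      sex_system = if (i == 4) "neo-XY" else "Xyp",
      b_min = 0L,
      b_max = if (i == 1) sample(1:4, 1) else sample(0:1, 1),
      sexpair_code = i - 1L,
      cband_code = sample(0:1, 1),
      dapi_code = sample(0:1, 1),
      cma3_code = sample(0:3, 1),
      nor_code = sample(0:3, 1)
    )
  })
  class(recs) <- c("karyotype_tbl", class(tibble::tibble()))
  recs
}
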