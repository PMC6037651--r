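test_that("single characters score their known lengths", {
  tr <- ape::read.tree(text = "((z,o),(out,(g,l)));")
  expect_identical(
    character_length(tr, c(z = 0, o = 0, g = 1, l = 1, out = 0)), 1L)
  expect_identical(
    character_length(tr, c(z = 2, o = 2, g = 2, l = 2, out = 2)), 0L)
})

test_that("ordered ladder characters match the brute-force oracle", {
  states <- c(z = 0, o = 1, g = 2, l = 3, out = 4)
  t1 <- ape::read.tree(text = "((z,o),(g,(l,out)));")
  t2 <- ape::read.tree(text = "((z,out),(o,(g,l)));")
  expect_identical(character_length(t1, states, ordered = TRUE), 4L)
  expect_identical(character_length(t2, states, ordered = TRUE), 6L)
  # frozen values above verified against exhaustive internal-state enumeration
  expect_identical(brute_force_length(t1, states, ordered = TRUE, K = 4), 4L)
  expect_identical(brute_force_length(t2, states, ordered = TRUE, K = 4), 6L)
})

test_that("Fitch and Sankoff agree with the oracle on random characters", {
  set.seed(11)
  taxa <- paste0("t", 1:5)
  trees <- enumerate_trees(taxa)
  for (i in 1:12) {
    tr <- trees[[sample(length(trees), 1)]]
    states <- setNames(sample(0:3, 5, replace = TRUE), taxa)
    if (i %% 4 == 0) states[sample(5, 1)] <- NA
    ordered <- i %% 2 == 0
    got <- character_length(tr, states, ordered = ordered)
    want <- brute_force_length(tr, states, ordered = ordered, K = 3)
    expect_identical(got, want)
  }
})

test_that("Fitch equals Sankoff under the all-unequal-cost-1 matrix", {
  set.seed(5)
  taxa <- paste0("t", 1:6)
  trees <- enumerate_trees(taxa)
  for (i in 1:10) {
    tr <- trees[[sample(length(trees), 1)]]
    K <- sample(1:4, 1)
    states <- matrix(sample(0:K, 6, replace = TRUE), ncol = 1,
                     dimnames = list(taxa, "c1"))
    s <- cytophylo:::phylo_to_structure(tr)
    fitch <- cytophylo:::fitch_engine(
      s, cytophylo:::fitch_leaf_masks(states))
    unit <- matrix(1, K + 1, K + 1) - diag(K + 1)
    sank <- cytophylo:::sankoff_engine(s, states, K, costm = unit)
    expect_identical(fitch, sank)
  }
})

test_that("tree length is the sum of per-character lengths", {
  cm <- sitophilus_matrix()
  tr <- ape::read.tree(text = fig4_rooted_newick)
  per <- tree_length(tr, cm, per_character = TRUE)
  expect_identical(sum(per$steps), tree_length(tr, cm))
  expect_identical(nrow(per), 20L)
})

test_that("lengths agree with phangorn's parsimony scores", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  for (seed in 1:4) {
    cm <- random_matrix(n_taxa = 6, n_char = 10, max_state = 2,
                        missing_frac = 0.1, seed = seed,
                        ordered = rep(FALSE, 10))
    trees <- enumerate_trees(taxa(cm))
    tr <- trees[[sample(length(trees), 1)]]
    chr <- cm$states
    mode(chr) <- "character"
    chr[is.na(chr)] <- "?"
    pd <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1", "2"),
                           ambiguity = "?")
    expect_identical(tree_length(tr, cm, treatment = "unordered"),
                     as.integer(phangorn::parsimony(tr, pd)))
    # ordered scoring against phangorn's Sankoff with the ladder cost matrix
    cmo <- char_matrix(cm$states, ordered = rep(TRUE, 10))
    ladder <- abs(outer(0:2, 0:2, "-"))
    dimnames(ladder) <- list(c("0", "1", "2"), c("0", "1", "2"))
    expect_equal(tree_length(tr, cmo, treatment = "ordered_multistate"),
                 as.integer(phangorn::parsimony(tr, pd, method = "sankoff",
                                                cost = ladder)))
  }
})

test_that("exhaustive search returns a verified global minimum", {
  cm <- sitophilus_matrix()
  res <- mp_search(cm)
  trees <- enumerate_trees(taxa(cm))
  lengths <- vapply(trees, tree_length, 1L, x = cm)
  expect_identical(res$length, min(lengths))
  expect_identical(length(res$structs), sum(lengths == min(lengths)))
})

test_that("the weevil matrix has a unique optimum matching the published tree", {
  res <- mp_search(sitophilus_matrix(), treatment = "ordered_multistate")
  expect_identical(length(res$newicks), 1L)
  rooted <- root_with_outgroup(mp_trees(res)[[1]], "Otiorhynchus_bisulcatus")
  expect_true(same_topology(rooted, ape::read.tree(text = fig4_rooted_newick)))
})

test_that("a matrix of constant characters ties all fifteen topologies at zero", {
  m <- matrix(1L, nrow = 5, ncol = 3,
              dimnames = list(paste0("t", 1:5), paste0("c", 1:3)))
  res <- mp_search(char_matrix(m))
  expect_identical(res$length, 0L)
  expect_identical(length(res$structs), 15L)
})

test_that("adding a constant character changes no tree ranking", {
  cm <- sitophilus_matrix()
  states2 <- cbind(cm$states, extra = 1L)
  cm2 <- char_matrix(states2, ordered = c(cm$ordered, FALSE),
                     outgroup = cm$outgroup)
  expect_identical(mp_search(cm)$newicks, mp_search(cm2)$newicks)
})

test_that("branch-and-bound returns exactly the exhaustive optimum set", {
  for (seed in 1:4) {
    cm <- random_matrix(n_taxa = 6, n_char = 8, max_state = 2,
                        missing_frac = 0.1, seed = seed)
    ex <- mp_search(cm, mode = "exhaustive")
    bb <- mp_search(cm, mode = "branch_and_bound")
    expect_identical(bb$length, ex$length)
    expect_identical(bb$newicks, ex$newicks)
  }
})

test_that("degenerate inputs are refused", {
  cm <- sitophilus_matrix()
  empty <- cm
  empty$states <- cm$states[, 0, drop = FALSE]
  empty$ordered <- logical(0)
  expect_error(mp_search(empty), "empty")
  expect_error(mp_search(char_matrix(matrix(0L, 3, 2,
    dimnames = list(letters[1:3], c("a", "b"))))), ">= 4 taxa")
})
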