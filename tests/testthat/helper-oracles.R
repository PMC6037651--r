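# Independent oracles and generators used across the suite.

# Brute-force small-parsimony length: enumerate every assignment of states
# 0..K to the internal nodes (and to missing leaves) of a binary tree and
# minimise the summed per-edge cost. Deliberately naive and independent of
# the package's Fitch/Sankoff code paths.
brute_force_length <- function(tree, states, ordered = FALSE, K = NULL) {
  stopifnot(inherits(tree, "phylo"))
  states <- states[tree$tip.label]
  if (is.null(K)) K <- max(states, na.rm = TRUE)
  cost <- if (ordered) {
    function(a, b) abs(a - b)
  } else {
    function(a, b) as.integer(a != b)
  }
  ntip <- length(tree$tip.label)
  nodes <- sort(unique(as.vector(tree$edge)))
  internal <- nodes[nodes > ntip]
  free_leaves <- which(is.na(states))
  vars <- c(internal, free_leaves)
  grid <- do.call(expand.grid, rep(list(0:K), length(vars)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(v) {
      if (v <= ntip && !v %in% free_leaves) return(states[v])
      grid[r, match(v, vars)]
    }
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tot <- tot + cost(assign_state(tree$edge[e, 1]),
                        assign_state(tree$edge[e, 2]))
    }
    best <- min(best, tot)
  }
  as.integer(best)
}

# random character matrix with seeded states
random_matrix <- function(n_taxa, n_char, max_state = 1,
                          missing_frac = 0, seed = 1, ordered = NULL) {
  set.seed(seed)
  m <- matrix(sample(0:max_state, n_taxa * n_char, replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("c", seq_len(n_char))))
  if (missing_frac > 0) {
    m[stats::runif(length(m)) < missing_frac] <- NA_integer_
  }
  char_matrix(m, ordered = ordered)
}

fig4_rooted_newick <- paste0(
  "(Otiorhynchus_bisulcatus,((Sitophilus_granarius,Sitophilus_linearis),",
  "(Sitophilus_oryzae,Sitophilus_zeamais)));"
)

# unrooted-topology equality: same taxa and identical bipartition sets
same_topology <- function(t1, t2) {
  setequal(t1$tip.label, t2$tip.label) &&
    ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
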