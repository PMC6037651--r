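# Small-parsimony engines.
#
# Both engines run on the nested structures of trees.R, vectorised across
# characters: Fitch state sets are integer bitmasks (state i -> bit i), and
# the Sankoff pass carries a (max state + 1) x n_char cost matrix per node
# with the linear ladder cost |i - j| between states.

BIG_COST <- 1e7

# leaf state-set bitmasks; missing entries get the full observed state set
fitch_leaf_masks <- function(states) {
  obs <- apply(states, 2, function(s) {
    s <- unique(s[!is.na(s)])
    if (length(s) == 0) 1L else sum(bitwShiftL(1L, s))
  })
  masks <- bitwShiftL(1L, states)  # NA stays NA
  masks <- matrix(masks, nrow = nrow(states),
                  dimnames = dimnames(states))
  for (j in seq_len(ncol(masks))) {
    masks[is.na(masks[, j]), j] <- obs[j]
  }
  storage.mode(masks) <- "integer"
  masks
}

# total Fitch changes per character for the tree (first, struct)
fitch_engine <- function(struct, masks) {
  nchar_ <- ncol(masks)
  changes <- integer(nchar_)
  rec <- function(node) {
    if (is_leaf(node)) return(masks[node, ])
    a <- rec(node[[1]])
    b <- rec(node[[2]])
    inter <- bitwAnd(a, b)
    z <- inter == 0L
    if (any(z)) {
      changes[z] <<- changes[z] + 1L
      inter[z] <- bitwOr(a, b)[z]
    }
    inter
  }
  rec(struct)
  changes
}

# minimal cost per character (Sankoff DP); default cost is the linear ladder
# |i - j|; missing = zero-cost vector
sankoff_engine <- function(struct, states, K, costm = NULL) {
  nchar_ <- ncol(states)
  nst <- K + 1L
  if (is.null(costm)) costm <- abs(outer(0:K, 0:K, "-"))
  stopifnot(nrow(costm) == nst, ncol(costm) == nst)
  leaf_cost <- function(name) {
    C <- matrix(BIG_COST, nrow = nst, ncol = nchar_)
    s <- states[name, ]
    miss <- is.na(s)
    if (any(!miss)) C[cbind(s[!miss] + 1L, which(!miss))] <- 0
    if (any(miss)) C[, miss] <- 0
    C
  }
  down <- function(C) {
    # D[i,] = min_j (cost(i,j) + C[j,])
    D <- matrix(0, nrow = nst, ncol = nchar_)
    for (i in seq_len(nst)) {
      best <- C[1, ] + costm[i, 1]
      if (nst > 1) for (j in 2:nst) {
        best <- pmin(best, C[j, ] + costm[i, j])
      }
      D[i, ] <- best
    }
    D
  }
  rec <- function(node) {
    if (is_leaf(node)) return(leaf_cost(node))
    down(rec(node[[1]])) + down(rec(node[[2]]))
  }
  C <- rec(struct)
  len <- C[1, ]
  if (nst > 1) for (j in 2:nst) len <- pmin(len, C[j, ])
  as.integer(round(len))
}

# per-character lengths of one full structure under a treatment
pars_lengths_struct <- function(full_struct, x, treatment) {
  ord <- effective_ordered(x, treatment)
  out <- integer(ncol(x$states))
  if (any(!ord)) {
    masks <- fitch_leaf_masks(x$states[, !ord, drop = FALSE])
    out[!ord] <- fitch_engine(full_struct, masks)
  }
  if (any(ord)) {
    sts <- x$states[, ord, drop = FALSE]
    K <- max(sts, na.rm = TRUE)
    if (!is.finite(K)) K <- 0L
    out[ord] <- sankoff_engine(full_struct, sts, as.integer(K))
  }
  out
}

# n_topologies x n_char matrix of lengths over an enumeration
score_topologies <- function(topo, x, treatment) {
  t(vapply(topo$structs, function(s) {
    pars_lengths_struct(new_node(topo$taxa[1], s), x, treatment)
  }, integer(ncol(x$states))))
}

#' Parsimony length of one character on a tree
#'
#' Exact minimum number of state changes of a single discrete character on
#' a binary tree: Fitch state-set passes for unordered characters, Sankoff
#' dynamic programming with ladder cost `|i - j|` for ordered ones. Missing
#' states are free (full observed state set / zero-cost vector).
#'
#' @param tree A binary `phylo` tree (rooted or unrooted).
#' @param states Named integer vector of character states, names covering
#'   the tree's tip labels; `NA` = missing.
#' @param ordered Should the character be scored on the linear ladder?
#' @return Integer number of steps.
#' @examples
#' tr <- ape::read.tree(text = "((z,o),(g,(l,out)));")
#' character_length(tr, c(z = 0, o = 0, g = 1, l = 1, out = 0))
#' @export
character_length <- function(tree, states, ordered = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(states))) {
    stop("states must be named for every tip of the tree")
  }
  m <- matrix(as.integer(states[tree$tip.label]), ncol = 1,
              dimnames = list(tree$tip.label, "char"))
  x <- char_matrix_raw(m, ordered = ordered)
  s <- phylo_to_structure(tree)
  pars_lengths_struct(s, x, "ordered_multistate")[1]
}

# char_matrix without the >=0 state check refusal on all-NA etc.
char_matrix_raw <- function(states, ordered) {
  structure(list(states = states, ordered = ordered, outgroup = NULL),
            class = "char_matrix")
}

#' Total parsimony length of a tree
#'
#' @param tree A binary `phylo` tree.
#' @param x A [char_matrix] covering the tree's tips.
#' @param treatment `"ordered_multistate"` (honour the matrix's ordered
#'   flags) or `"unordered"` (Fitch throughout).
#' @param per_character If `TRUE`, return a tibble of per-character steps
#'   instead of the total.
#' @return Integer total length, or a tibble with columns `character`,
#'   `steps`.
#' @export
tree_length <- function(tree, x, treatment = c("ordered_multistate", "unordered"),
                        per_character = FALSE) {
  stopifnot(inherits(x, "char_matrix"))
  treatment <- match.arg(treatment)
  if (!all(tree$tip.label %in% taxa(x))) {
    stop("matrix does not cover the tree's tips")
  }
  s <- phylo_to_structure(tree)
  len <- pars_lengths_struct(s, x, treatment)
  if (per_character) {
    tibble::tibble(character = colnames(x$states), steps = len)
  } else {
    sum(len)
  }
}

#' Exact maximum-parsimony search
#'
#' Finds all minimum-length unrooted binary topologies for a character
#' matrix, either by exhaustive enumeration of all (2n-5)!! topologies or by
#' branch-and-bound (exact; prunes partial trees whose length already
#' exceeds the best complete tree). Ties are preserved: every optimal
#' topology is returned, sorted by canonical Newick.
#'
#' @param x A [char_matrix] with at least 4 taxa.
#' @param treatment `"ordered_multistate"` or `"unordered"` (see
#'   [tree_length()]).
#' @param mode `"exhaustive"` or `"branch_and_bound"`.
#' @param cap Taxon cap for exhaustive enumeration (default 9).
#' @return An object of class `mp_result`; see [tidy.mp_result()] and
#'   [glance.mp_result()].
#' @examples
#' res <- mp_search(sitophilus_matrix())
#' glance(res)
#' @export
mp_search <- function(x, treatment = c("ordered_multistate", "unordered"),
                      mode = c("exhaustive", "branch_and_bound"), cap = 9) {
  stopifnot(inherits(x, "char_matrix"))
  treatment <- match.arg(treatment)
  mode <- match.arg(mode)
  if (ncol(x$states) == 0) stop("empty character matrix")
  if (nrow(x$states) < 4) stop("maximum-parsimony search needs >= 4 taxa")
  tx <- sort(taxa(x))

  if (mode == "exhaustive") {
    topo <- enum_topologies(tx, cap = cap)
    L <- score_topologies(topo, x, treatment)
    totals <- rowSums(L)
    best <- min(totals)
    keep <- which(totals == best)
    structs <- topo$structs[keep]
    n_searched <- length(topo$structs)
  } else {
    res <- bnb_search(tx, x, treatment)
    structs <- res$structs
    best <- res$len
    n_searched <- res$visited
  }

  newicks <- vapply(structs, canonical_newick, "", first = tx[1])
  ord <- order(newicks)
  structs <- structs[ord]
  newicks <- newicks[ord]
  idx <- taxon_index(tx)
  out <- list(
    taxa = tx,
    structs = structs,
    newicks = newicks,
    splits = lapply(structs, struct_splits, index = idx),
    length = as.integer(best),
    treatment = treatment,
    mode = mode,
    n_searched = n_searched,
    n_characters = ncol(x$states),
    outgroup = x$outgroup
  )
  class(out) <- "mp_result"
  out
}

bnb_search <- function(tx, x, treatment) {
  first <- tx[1]
  rest <- tx[-1]
  n <- length(tx)
  env <- new.env()
  env$best <- Inf
  env$structs <- list()
  env$visited <- 0L
  rec <- function(s, k) {
    len <- sum(pars_lengths_struct(new_node(first, s), x, treatment))
    if (len > env$best) return()
    if (k == n) {
      env$visited <- env$visited + 1L
      if (len < env$best) {
        env$best <- len
        env$structs <- list(s)
      } else {
        env$structs <- c(env$structs, list(s))
      }
      return()
    }
    for (g in graft_all(s, rest[k])) rec(g, k + 1L)
  }
  rec(rest[1], 2L)
  list(structs = env$structs, len = env$best, visited = env$visited)
}

#' All maximum-parsimony trees of a search result
#'
#' @param x An `mp_result`.
#' @return A `multiPhylo` of the tied optimal topologies.
#' @export
mp_trees <- function(x) {
  stopifnot(inherits(x, "mp_result"))
  as_multiphylo(ape::read.tree(text = paste(x$newicks, collapse = "\n")))
}

as_multiphylo <- function(tr) {
  if (inherits(tr, "phylo")) {
    tr <- structure(list(tr), class = "multiPhylo")
  }
  tr
}

#' @export
print.mp_result <- function(x, ...) {
  cat("<mp_result> ", length(x$structs), " optimal topolog",
      if (length(x$structs) == 1) "y" else "ies",
      " of length ", x$length, " (", x$mode, ", ", x$treatment, ")\n",
      sep = "")
  for (nw in x$newicks) cat("  ", nw, "\n", sep = "")
  invisible(x)
}

#' Tidy a parsimony search result
#'
#' @param x An `mp_result`.
#' @param ... Unused.
#' @return A tibble with one row per optimal topology: `tree`, `newick`,
#'   `length`.
#' @export
tidy.mp_result <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$newicks),
    newick = x$newicks,
    length = x$length
  )
}

#' One-row summary of a parsimony search
#'
#' @param x An `mp_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mp_result <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_characters = x$n_characters,
    treatment = x$treatment,
    mode = x$mode,
    n_trees_searched = x$n_searched,
    n_mp_trees = length(x$structs),
    min_length = x$length
  )
}
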