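# Internal tree machinery.
#
# Unrooted binary topologies over a taxon set are enumerated by stepwise
# addition and represented as nested "structures": the topology is rooted on
# the pendant edge of the first (sorted) taxon, whose removal leaves a rooted
# binary tree over the remaining taxa. A structure is either a taxon name
# (leaf) or a list of two child structures. This form makes small-parsimony
# scoring a plain binary recursion and makes the nontrivial bipartitions the
# internal leaf-sets of the structure.

new_node <- function(a, b) list(a, b)
is_leaf <- function(s) is.character(s)

# all ways to graft `x` onto tree `s`, including above the root of s
graft_all <- function(s, x) {
  out <- list(new_node(s, x))
  if (!is_leaf(s)) {
    for (l in graft_all(s[[1]], x)) out <- c(out, list(new_node(l, s[[2]])))
    for (r in graft_all(s[[2]], x)) out <- c(out, list(new_node(s[[1]], r)))
  }
  out
}

# structures over taxa[-1]; together with taxa[1] each is one unrooted topology
enum_structures <- function(taxa) {
  rest <- taxa[-1]
  trees <- list(rest[1])
  for (x in rest[-1]) {
    trees <- unlist(lapply(trees, graft_all, x = x), recursive = FALSE)
  }
  trees
}

struct_newick <- function(s) {
  if (is_leaf(s)) s else {
    paste0("(", struct_newick(s[[1]]), ",", struct_newick(s[[2]]), ")")
  }
}

full_newick <- function(s, first) {
  paste0("(", first, ",", struct_newick(s), ");")
}

# canonical form: subtrees ordered by their smallest taxon label
canon_struct <- function(s) {
  if (is_leaf(s)) return(list(s = s, min = s))
  a <- canon_struct(s[[1]])
  b <- canon_struct(s[[2]])
  if (a$min <= b$min) list(s = new_node(a$s, b$s), min = a$min)
  else list(s = new_node(b$s, a$s), min = b$min)
}

canonical_newick <- function(s, first) full_newick(canon_struct(s)$s, first)

# leaf sets under internal nodes of s, as taxon-index bitmasks (bit i-1 set
# for taxa[i]); excludes the set under the root (trivial). These are exactly
# the nontrivial splits of the unrooted topology, canonical side = the side
# not containing taxa[1].
struct_splits <- function(s, index) {
  masks <- integer(0)
  rec <- function(node) {
    if (is_leaf(node)) return(bitwShiftL(1L, index[[node]] - 1L))
    m <- bitwOr(rec(node[[1]]), rec(node[[2]]))
    masks <<- c(masks, m)
    m
  }
  rec(s)
  if (length(masks) > 0) masks <- masks[-length(masks)]
  masks
}

taxon_index <- function(taxa) stats::setNames(as.list(seq_along(taxa)), taxa)

split_to_taxa <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftL(1L, seq_along(taxa) - 1L), mask) != 0L]
}

split_label <- function(mask, taxa) {
  paste(sort(split_to_taxa(mask, taxa)), collapse = "|")
}

# enumerate topologies with newick strings and split masks; taxa are sorted
enum_topologies <- function(taxa, cap = 9) {
  taxa <- sort(unique(taxa))
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  if (n > cap) {
    stop("exhaustive enumeration capped at ", cap,
         " taxa; use branch-and-bound search instead")
  }
  if (n > 31) stop("taxon bitmasks limited to 31 taxa")
  structs <- enum_structures(taxa)
  idx <- taxon_index(taxa)
  list(
    taxa = taxa,
    structs = structs,
    newicks = vapply(structs, canonical_newick, "", first = taxa[1]),
    splits = lapply(structs, struct_splits, index = idx)
  )
}

#' Enumerate all unrooted binary tree topologies
#'
#' Produces every distinct unrooted binary topology over the taxon set by
#' stepwise addition over the sorted taxon list, exactly (2n-5)!! trees,
#' each once, in deterministic order. Trees are returned rooted arbitrarily
#' on the first taxon's pendant edge (parsimony lengths and splits are
#' unaffected by this representation).
#'
#' @param taxa Character vector of 3 or more taxon names.
#' @param cap Maximum number of taxa accepted (default 9); above the cap the
#'   search space should be explored with [mp_search()]'s branch-and-bound
#'   mode instead.
#' @return A `multiPhylo` object.
#' @examples
#' length(enumerate_trees(c("a", "b", "c", "d", "e")))  # 15
#' @export
enumerate_trees <- function(taxa, cap = 9) {
  topo <- enum_topologies(taxa, cap = cap)
  as_multiphylo(ape::read.tree(text = paste(topo$newicks, collapse = "\n")))
}

# phylo -> structure (+ original taxa), errors on non-binary interior
phylo_to_structure <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  build <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    kids <- children[[as.character(v)]]
    if (length(kids) == 2) {
      new_node(build(kids[1]), build(kids[2]))
    } else {
      stop("binary tree required")
    }
  }
  kids <- children[[as.character(root)]]
  if (length(kids) == 2) {
    new_node(build(kids[1]), build(kids[2]))
  } else if (length(kids) == 3) {
    # unrooted representation: bisect arbitrarily
    new_node(build(kids[1]), new_node(build(kids[2]), build(kids[3])))
  } else {
    stop("binary tree required")
  }
}

phylo_splits <- function(tree, taxa) {
  s <- phylo_to_structure(tree)
  # rebase so that canonical side excludes taxa[1]
  idx <- taxon_index(taxa)
  masks <- integer(0)
  full <- sum(bitwShiftL(1L, seq_along(taxa) - 1L))
  rec <- function(node) {
    if (is_leaf(node)) return(bitwShiftL(1L, idx[[node]] - 1L))
    m <- bitwOr(rec(node[[1]]), rec(node[[2]]))
    masks <<- c(masks, m)
    m
  }
  rec(s)
  masks <- masks[-length(masks)]
  bit1 <- 1L
  masks <- ifelse(bitwAnd(masks, bit1) != 0L, bitwAnd(full, bitwNot(masks)),
                  masks)
  sz <- vapply(masks, function(m) sum(bitwAnd(bitwShiftL(1L, seq_along(taxa) - 1L), m) != 0L), 1L)
  unique(masks[sz >= 2 & sz <= length(taxa) - 2])
}

# build an unrooted topology (as phylo) from pairwise-compatible canonical
# split masks; polytomies where splits are absent
build_tree_from_splits <- function(taxa, masks, labels = NULL,
                                   root_child = NULL) {
  idx <- seq_along(taxa)
  ord <- order(vapply(masks, mask_size, 1L, n = length(taxa)))
  masks <- masks[ord]
  if (!is.null(labels)) labels <- labels[ord]
  items <- stats::setNames(as.list(taxa[-1]), NULL)
  item_masks <- bitwShiftL(1L, idx[-1] - 1L)
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    inside <- bitwAnd(item_masks, m) != 0L
    if (any(bitwAnd(item_masks[inside], bitwNot(m)) != 0L)) {
      stop("incompatible splits")
    }
    grp <- paste(unlist(items[inside]), collapse = ",")
    lab <- if (!is.null(labels)) labels[[k]] else ""
    items <- c(items[!inside], list(paste0("(", grp, ")", lab)))
    item_masks <- c(item_masks[!inside], m)
  }
  nwk <- paste0("(", taxa[1], ",", paste(unlist(items), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

mask_size <- function(mask, n) {
  sum(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), mask) != 0L)
}

#' Strict consensus of trees
#'
#' Returns the tree containing exactly the nontrivial bipartitions present
#' in every input tree; with disagreement, the result has polytomies, down
#' to a fully unresolved star.
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees over the same
#'   taxa.
#' @return A `phylo` tree (possibly non-binary).
#' @examples
#' tr <- enumerate_trees(letters[1:5])
#' strict_consensus(tr[1:2])
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1) stop("need at least one tree")
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) stop("trees must share one taxon set")
  }
  shared <- Reduce(intersect, lapply(trees, phylo_splits, taxa = taxa))
  build_tree_from_splits(taxa, as.list(shared))
}

#' Root a tree on its outgroup
#'
#' Places the root on the outgroup's pendant edge, so the outgroup is the
#' sister lineage of the whole ingroup; ingroup structure is preserved.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Taxon name present in the tree.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not in the tree")
  }
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(out$node.label)) {
    out$node.label[out$node.label == "Root"] <- ""
  }
  out
}

#' Write a tree to a Newick file
#'
#' Support values, when present as integer node labels, are carried along.
#'
#' @param tree A `phylo` tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
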