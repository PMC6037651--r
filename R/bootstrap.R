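#' Resample characters with replacement
#'
#' Draws `n_char` characters uniformly with replacement from the matrix (the
#' nonparametric bootstrap resampling step). Ordered flags travel with the
#' drawn characters. Deterministic for a fixed seed.
#'
#' @param x A [char_matrix] with at least one character.
#' @param seed Integer RNG seed.
#' @return A [char_matrix] with the same taxa and character count.
#' @export
resample_matrix <- function(x, seed = 1) {
  stopifnot(inherits(x, "char_matrix"))
  k <- ncol(x$states)
  if (k < 1) stop("matrix has no characters")
  set.seed(seed)
  idx <- sample.int(k, k, replace = TRUE)
  states <- x$states[, idx, drop = FALSE]
  colnames(states) <- make.unique(colnames(x$states)[idx])
  char_matrix(states, ordered = x$ordered[idx], outgroup = x$outgroup)
}

#' Nonparametric bootstrap split support
#'
#' Estimates absolute-frequency bootstrap support for every bipartition:
#' each replicate resamples the characters with replacement and runs an
#' exact maximum-parsimony search; a replicate supports a split when the
#' split appears in the strict consensus of that replicate's set of optimal
#' trees (`tie_rule = "strict"`, the default, conservative under ties) or,
#' with `tie_rule = "fractional"`, contributes the fraction of the
#' replicate's tied trees containing the split. Support is 100 x
#' (contributions / replicates).
#'
#' Replicates only reweight the characters, so for exhaustively searchable
#' matrices the per-topology, per-character lengths are scored once and each
#' replicate reduces to a multinomial reweighting — the search is still
#' exact for every replicate.
#'
#' @param x A [char_matrix] with >= 4 taxa.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param treatment `"ordered_multistate"` or `"unordered"` (see
#'   [tree_length()]).
#' @param seed Integer RNG seed; the whole result is reproducible
#'   bit-for-bit for a fixed seed.
#' @param tie_rule `"strict"` or `"fractional"` (see above).
#' @param cap Taxon cap for the exhaustive enumeration.
#' @return An object of class `boot_support`: use [tidy.boot_support()] for
#'   the split-by-split table.
#' @examples
#' bs <- bootstrap_support(sitophilus_matrix(), replicates = 200, seed = 1)
#' tidy(bs)
#' @export
bootstrap_support <- function(x, replicates = 100000,
                              treatment = c("ordered_multistate", "unordered"),
                              seed = 1, tie_rule = c("strict", "fractional"),
                              cap = 9) {
  stopifnot(inherits(x, "char_matrix"))
  treatment <- match.arg(treatment)
  tie_rule <- match.arg(tie_rule)
  if (replicates < 1) stop("replicates must be >= 1")
  if (nrow(x$states) < 4) stop("bootstrap needs >= 4 taxa")
  k <- ncol(x$states)
  tx <- sort(taxa(x))
  n <- length(tx)

  topo <- enum_topologies(tx, cap = cap)
  L <- score_topologies(topo, x, treatment)      # n_topo x n_char
  n_topo <- nrow(L)

  # all possible nontrivial splits and each topology's membership
  all_masks <- sort(unique(unlist(topo$splits)))
  memb <- vapply(topo$splits, function(sp) all_masks %in% sp,
                 logical(length(all_masks)))      # n_split x n_topo

  set.seed(seed)
  counts <- stats::rmultinom(replicates, size = k, prob = rep(1 / k, k))
  totals <- t(L) ; totals <- crossprod(totals, counts)  # n_topo x replicates
  minlen <- do.call(pmin, lapply(seq_len(n_topo), function(i) totals[i, ]))
  tied <- totals == rep(minlen, each = n_topo)    # n_topo x replicates

  support <- numeric(length(all_masks))
  if (tie_rule == "strict") {
    # split in strict consensus <=> no tied topology lacks it
    for (s in seq_along(all_masks)) {
      lacking <- !memb[s, ]
      support[s] <- mean(colSums(tied & lacking) == 0L)
    }
  } else {
    n_tied <- colSums(tied)
    for (s in seq_along(all_masks)) {
      support[s] <- mean(colSums(tied & memb[s, ]) / n_tied)
    }
  }

  out <- list(
    taxa = tx,
    masks = all_masks,
    support = 100 * support,
    replicates = as.integer(replicates),
    seed = seed,
    treatment = treatment,
    tie_rule = tie_rule,
    outgroup = x$outgroup
  )
  class(out) <- "boot_support"
  out
}

#' Support of one split
#'
#' @param x A `boot_support` object.
#' @param side Character vector of taxon names forming one side of the
#'   bipartition.
#' @return Support percentage in `[0, 100]` (0 for a split never seen).
#' @examples
#' bs <- bootstrap_support(sitophilus_matrix(), replicates = 200, seed = 1)
#' split_support(bs, c("Sitophilus_zeamais", "Sitophilus_oryzae"))
#' @export
split_support <- function(x, side) {
  stopifnot(inherits(x, "boot_support"))
  bad <- setdiff(side, x$taxa)
  if (length(bad) > 0) stop("unknown taxa: ", paste(bad, collapse = ", "))
  mask <- sum(bitwShiftL(1L, match(side, x$taxa) - 1L))
  full <- sum(bitwShiftL(1L, seq_along(x$taxa) - 1L))
  if (bitwAnd(mask, 1L) != 0L) mask <- bitwAnd(full, bitwNot(mask))
  i <- match(mask, x$masks)
  if (is.na(i)) 0 else x$support[i]
}

#' @export
print.boot_support <- function(x, ...) {
  cat("<boot_support> ", x$replicates, " replicates, ", x$treatment,
      ", ties: ", x$tie_rule, ", seed ", x$seed, "\n", sep = "")
  print(tidy(x), n = 10)
  invisible(x)
}

#' Tidy bootstrap support into a split table
#'
#' @param x A `boot_support` object.
#' @param ... Unused.
#' @return A tibble with columns `split` (taxa on the side excluding the
#'   first taxon, `|`-separated) and `support` (percent), sorted by
#'   decreasing support.
#' @export
tidy.boot_support <- function(x, ...) {
  out <- tibble::tibble(
    split = vapply(x$masks, split_label, "", taxa = x$taxa),
    support = x$support
  )
  dplyr::arrange(out, dplyr::desc(.data$support))
}

#' @export
glance.boot_support <- function(x, ...) {
  tibble::tibble(
    replicates = x$replicates, seed = x$seed, treatment = x$treatment,
    tie_rule = x$tie_rule, n_splits_seen = sum(x$support > 0)
  )
}

#' Annotate a tree with bootstrap support and collapse weak nodes
#'
#' Labels each internal node with its (rounded) split support and collapses
#' to a polytomy every node whose support does not exceed the threshold.
#'
#' @param tree A rooted `phylo` tree.
#' @param result A `boot_support` object over the same taxa.
#' @param threshold Collapse threshold in percent (default 50: only nodes
#'   with support strictly above 50 are retained).
#' @return A rooted `phylo` tree with integer node labels.
#' @export
annotate_and_collapse <- function(tree, result, threshold = 50) {
  stopifnot(inherits(tree, "phylo"), inherits(result, "boot_support"))
  if (!setequal(tree$tip.label, result$taxa)) {
    stop("tree and bootstrap result cover different taxa")
  }
  tx <- result$taxa
  masks <- phylo_splits(tree, tx)
  sup <- vapply(masks, function(m) {
    i <- match(m, result$masks)
    if (is.na(i)) 0 else result$support[i]
  }, 1.0)
  keep <- sup > threshold
  out <- build_tree_from_splits(tx, as.list(masks[keep]),
                                labels = as.character(round(sup[keep])))
  og <- result$outgroup
  if (!is.null(og) && og %in% tx) out <- root_with_outgroup(out, og)
  out
}

#' Bar chart of bootstrap split support
#'
#' @param object A `boot_support` object.
#' @param threshold Reference line (percent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boot_support <- function(object, threshold = 50, ...) {
  df <- tidy(object)
  df$split <- factor(df$split, levels = rev(df$split))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$split)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "bootstrap support (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
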