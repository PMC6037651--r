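#' Pipeline configuration
#'
#' Collects every knob of the full analysis into one validated list. Inputs
#' may be in-memory objects or file paths; file outputs are written under
#' `out_dir` when it is set.
#'
#' @param matrix A [char_matrix], or a path to a character-matrix file
#'   (CSV or NEXUS); ignored when `records` is given.
#' @param records A karyotype record table (or CSV path) to encode with
#'   `scheme`.
#' @param scheme Optional [coding_scheme()] used with `records`.
#' @param outgroup Outgroup taxon (default: the matrix's own).
#' @param treatment Character treatment for parsimony (see [tree_length()]).
#' @param replicates Bootstrap replicates (default 100000).
#' @param threshold Collapse threshold in percent (default 50).
#' @param seed Integer seed for the bootstrap.
#' @param tie_rule Bootstrap tie handling (see [bootstrap_support()]).
#' @param flow_runs Optional named list of flow-run data frames (or CSV
#'   paths with a `fluorescence` column) for genome-size estimation.
#' @param standard_is Which flow peak is the internal standard
#'   (`"lower"`/`"upper"`).
#' @param standard_1c_mbp 1C of the internal standard (Mbp).
#' @param mbp_per_pg Unit-conversion constant.
#' @param out_dir Output directory (created if needed), or `NULL` for no
#'   file output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix = NULL, records = NULL, scheme = NULL,
                            outgroup = NULL,
                            treatment = c("ordered_multistate", "unordered"),
                            replicates = 100000, threshold = 50, seed = 1,
                            tie_rule = c("strict", "fractional"),
                            flow_runs = NULL,
                            standard_is = c("lower", "upper"),
                            standard_1c_mbp = 328,
                            mbp_per_pg = MBP_PER_PG,
                            out_dir = NULL) {
  stopifnot(replicates >= 1, threshold >= 0, threshold <= 100)
  structure(
    list(matrix = matrix, records = records, scheme = scheme,
         outgroup = outgroup, treatment = match.arg(treatment),
         replicates = as.integer(replicates), threshold = threshold,
         seed = as.integer(seed), tie_rule = match.arg(tie_rule),
         flow_runs = flow_runs, standard_is = match.arg(standard_is),
         standard_1c_mbp = standard_1c_mbp, mbp_per_pg = mbp_per_pg,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Encode (or load) the character matrix, search for all maximum-parsimony
#' trees, estimate bootstrap split support, root on the outgroup and
#' collapse weakly supported nodes, and (optionally) estimate genome sizes
#' from flow runs. Identical configurations produce identical bundles and
#' files; the run log records seed, treatment and parameters.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle` with elements `matrix`,
#'   `informative`, `mp`, `consensus`, `bootstrap`, `tree` (annotated,
#'   rooted), `tree_newick`, `genome_sizes` (or `NULL`), `log`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(matrix = sitophilus_matrix(), replicates = 1000)
#' bundle <- run_pipeline(cfg)
#' bundle$tree_newick
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  cm <- stage("read_matrix", {
    if (!is.null(config$records)) {
      recs <- if (is.character(config$records)) {
        read_karyotypes(config$records)
      } else config$records
      encode_karyotypes(recs, scheme = config$scheme,
                        outgroup = config$outgroup)
    } else if (is.character(config$matrix)) {
      if (!file.exists(config$matrix)) {
        stop("input file not found: ", config$matrix)
      }
      read_character_matrix(config$matrix)
    } else if (inherits(config$matrix, "char_matrix")) {
      config$matrix
    } else {
      stop("config needs either 'matrix' or 'records'")
    }
  })
  outgroup <- config$outgroup %||% cm$outgroup

  info <- stage("classify_informative", count_informative(cm))
  mp <- stage("mp_search",
              mp_search(cm, treatment = config$treatment))
  cons <- stage("consensus", strict_consensus(mp_trees(mp)))
  bs <- stage("bootstrap", bootstrap_support(
    cm, replicates = config$replicates, treatment = config$treatment,
    seed = config$seed, tie_rule = config$tie_rule))
  tree <- stage("annotate", {
    t0 <- if (!is.null(outgroup)) root_with_outgroup(cons, outgroup) else cons
    bs2 <- bs
    bs2$outgroup <- outgroup
    annotate_and_collapse(t0, bs2, threshold = config$threshold)
  })
  tree_newick <- ape::write.tree(tree)

  genome <- NULL
  if (!is.null(config$flow_runs)) {
    genome <- stage("genome_size", {
      runs <- lapply(config$flow_runs, function(r) {
        if (is.character(r)) utils::read.csv(r, stringsAsFactors = FALSE) else r
      })
      ests <- purrr::map_dfr(runs, flow_genome_size,
                             standard_is = config$standard_is,
                             standard_1c_mbp = config$standard_1c_mbp,
                             mbp_per_pg = config$mbp_per_pg)
      genome_size_report(ests, mbp_per_pg = config$mbp_per_pg)
    })
  }

  log <- c(
    paste0("cytophylo ", as.character(utils::packageVersion("cytophylo"))),
    paste0("seed: ", config$seed),
    paste0("treatment: ", config$treatment),
    paste0("bootstrap replicates: ", config$replicates),
    paste0("tie rule: ", config$tie_rule),
    paste0("collapse threshold: ", config$threshold),
    paste0("outgroup: ", outgroup %||% "(none)"),
    paste0("taxa: ", paste(taxa(cm), collapse = ", ")),
    paste0("characters: ", ncol(cm$states)),
    paste0("informative (pattern rule, all / binary): ",
           info$n_informative[1], " / ", info$n_informative[2]),
    paste0("MP length: ", mp$length, " (", length(mp$structs),
           " optimal topologies)"),
    paste0("annotated tree: ", tree_newick)
  )

  bundle <- structure(
    list(matrix = cm, informative = info, mp = mp, consensus = cons,
         bootstrap = bs, tree = tree, tree_newick = tree_newick,
         genome_sizes = genome, log = log),
    class = "pipeline_bundle"
  )

  if (!is.null(config$out_dir)) {
    stage("write_outputs", write_bundle(bundle, config$out_dir))
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_character_matrix(bundle$matrix,
                         file.path(out_dir, "matrix_echo.csv"), "csv")
  writeLines(bundle$mp$newicks, file.path(out_dir, "mp_trees.nwk"))
  write_tree(bundle$tree, file.path(out_dir, "boot_tree.nwk"))
  utils::write.table(tidy(bundle$bootstrap),
                     file.path(out_dir, "split_support.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$genome_sizes)) {
    utils::write.table(bundle$genome_sizes,
                       file.path(out_dir, "genome_size.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(x$log, sep = "\n")
  invisible(x)
}
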