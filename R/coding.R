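#' Karyotype-feature coding schemes
#'
#' A coding scheme fixes how karyotype records are translated into discrete
#' characters: which diploid numbers, female-complement metacentric counts
#' and submetacentric counts get their own presence/absence character (and in
#' what order), and how X and Y morphology classes map to ordinal states.
#' Each structural rearrangement product observed in the record set is one
#' character; graded multistate characters (sexual-pair ordinal, Y
#' morphology, CMA3, NOR) default to ordered, binary characters to unordered.
#'
#' `derive_coding_scheme()` builds a scheme from a record set (categories in
#' first-observation order over the records); `sitophilus_coding_scheme()`
#' returns the packaged scheme for the weevil study, whose category order
#' follows the published feature table.
#'
#' @param records A tibble of karyotype records.
#' @return A list of class `coding_scheme`.
#' @export
derive_coding_scheme <- function(records) {
  fc <- female_class_counts(records)
  extra <- parse_extras(records$extra_categories)
  meta_obs <- sub_obs <- integer(0)
  for (i in seq_len(nrow(records))) {
    meta_obs <- c(meta_obs, fc[i, "metacentric"], extra[[i]][["metacentric"]])
    sub_obs <- c(sub_obs, fc[i, "submetacentric"],
                 extra[[i]][["submetacentric"]])
  }
  coding_scheme(
    diploid_numbers = sort(unique(records$diploid_number)),
    metacentric_counts = unique(meta_obs),
    submetacentric_counts = unique(sub_obs),
    x_state_map = class_state_map(records$x_class),
    y_state_map = class_state_map(records$y_class)
  )
}

class_state_map <- function(classes) {
  u <- unique(classes)
  stats::setNames(seq_along(u) - 1L, u)
}

#' @rdname derive_coding_scheme
#' @param diploid_numbers Integer vector; state = position in this list - 1.
#' @param metacentric_counts,submetacentric_counts Integer vectors of
#'   female-complement counts, one presence/absence character each, in order.
#' @param x_state_map,y_state_map Named integer vectors mapping morphology
#'   classes to states.
#' @export
coding_scheme <- function(diploid_numbers, metacentric_counts,
                          submetacentric_counts, x_state_map, y_state_map) {
  structure(
    list(diploid_numbers = as.integer(diploid_numbers),
         metacentric_counts = as.integer(metacentric_counts),
         submetacentric_counts = as.integer(submetacentric_counts),
         x_state_map = x_state_map, y_state_map = y_state_map),
    class = "coding_scheme"
  )
}

#' @rdname derive_coding_scheme
#' @export
sitophilus_coding_scheme <- function() {
  coding_scheme(
    diploid_numbers = c(22L, 24L),
    metacentric_counts = c(22L, 20L, 18L, 16L),
    submetacentric_counts = c(0L, 2L, 8L, 6L, 4L),
    x_state_map = c(submetacentric = 0L, metacentric = 1L),
    y_state_map = c("dot-like" = 0L, metacentric = 1L, subtelocentric = 2L)
  )
}

parse_extras <- function(extra) {
  lapply(extra, function(s) {
    out <- list(metacentric = integer(0), submetacentric = integer(0))
    if (is.na(s) || !nzchar(s)) return(out)
    for (tok in strsplit(s, ";")[[1]]) {
      kv <- strsplit(trimws(tok), ":")[[1]]
      if (length(kv) != 2) stop("malformed extra category: '", tok, "'")
      out[[kv[1]]] <- c(out[[kv[1]]], as.integer(kv[2]))
    }
    out
  })
}

#' Encode karyotype records as a discrete character matrix
#'
#' Translates a set of karyotype records into presence/absence and graded
#' multistate characters, one per structural rearrangement category of the
#' coding scheme: diploid-number state, B-chromosome presence, Xyp presence,
#' one character per metacentric count and per submetacentric count of the
#' female complement (autosomes plus two X copies), telocentric-range
#' presence (the subtelocentric/telocentric classes), the ordinal
#' sexual-pair character, X and Y morphology, and the C-band/DAPI/CMA3/NOR
#' pattern codes. Unknown codes become missing (`?`).
#'
#' @param records A tibble of valid karyotype records (>= 2 rows, unique
#'   species).
#' @param scheme A `coding_scheme`; default derived from `records`.
#' @param outgroup Optional taxon name marked as outgroup in the result.
#' @return A [char_matrix] with one row per species, characters in scheme
#'   order.
#' @examples
#' m <- encode_karyotypes(sitophilus_karyotypes(),
#'                        scheme = sitophilus_coding_scheme(),
#'                        outgroup = "Otiorhynchus_bisulcatus")
#' glance(m)
#' @export
encode_karyotypes <- function(records, scheme = NULL, outgroup = NULL) {
  if (nrow(records) < 2) stop("need at least 2 records to encode")
  if (anyDuplicated(records$species)) stop("duplicate species names")
  chk <- validate_karyotype(records)
  if (!all(chk$valid)) {
    stop("invalid karyotype record(s): ",
         paste(chk$species[!chk$valid], collapse = ", "))
  }
  scheme <- scheme %||% derive_coding_scheme(records)
  fc <- female_class_counts(records)
  extra <- parse_extras(records$extra_categories)
  n <- nrow(records)

  cols <- list()
  cols[["Number of chromosomes"]] <-
    match(records$diploid_number, scheme$diploid_numbers) - 1L
  cols[["Presence of B chromosomes"]] <- as.integer(records$b_max > 0)
  cols[["Sex-chromosome system (Xyp)"]] <-
    as.integer(records$sex_system == "Xyp")
  for (k in scheme$metacentric_counts) {
    cols[[paste(k, "metacentric chromosomes")]] <- vapply(seq_len(n), function(i) {
      as.integer(fc[i, "metacentric"] == k ||
                   k %in% extra[[i]][["metacentric"]])
    }, 1L)
  }
  for (k in scheme$submetacentric_counts) {
    cols[[paste(k, "submetacentric chromosomes")]] <- vapply(seq_len(n), function(i) {
      as.integer(fc[i, "submetacentric"] == k ||
                   k %in% extra[[i]][["submetacentric"]])
    }, 1L)
  }
  telo_range <- c("subtelocentric", "telocentric")
  cols[["1 telocentric chromosome"]] <- as.integer(
    rowSums(fc[, telo_range, drop = FALSE]) > 0 |
      records$y_class %in% telo_range
  )
  cols[["Number of the sexual pair"]] <- records$sexpair_code
  cols[["Morphology of the X chromosome"]] <-
    map_states(records$x_class, scheme$x_state_map, "X")
  cols[["Morphology of the y chromosome"]] <-
    map_states(records$y_class, scheme$y_state_map, "y")
  cols[["C-band pattern"]] <- records$cband_code
  cols[["DAPI distribution"]] <- records$dapi_code
  cols[["CMA3 distribution"]] <- records$cma3_code
  cols[["NOR localization (FISH)"]] <- records$nor_code

  states <- do.call(cbind, cols)
  rownames(states) <- records$species
  char_matrix(states, outgroup = outgroup)
}

map_states <- function(classes, map, which) {
  unknown <- setdiff(unique(classes), names(map))
  if (length(unknown) > 0) {
    stop("no ", which, "-morphology state for class: ",
         paste(unknown, collapse = ", "))
  }
  unname(map[classes])
}

#' Packaged character matrix of the weevil karyotype features
#'
#' The 5-taxon, 20-character matrix of karyotype features for the four
#' *Sitophilus* species and the outgroup *Otiorhynchus bisulcatus*, as read
#' from the packaged CSV fixture. Equal, cell for cell, to
#' `encode_karyotypes(sitophilus_karyotypes(), sitophilus_coding_scheme())`.
#'
#' @return A [char_matrix].
#' @export
sitophilus_matrix <- function() {
  path <- system.file("extdata", "sitophilus_char_matrix.csv",
                      package = "cytophylo", mustWork = TRUE)
  read_character_matrix(path)
}

#' Classify characters as parsimony-informative
#'
#' Two criteria are available:
#'
#' * `"pattern"` — a character is informative iff at least two of its states
#'   each occur in at least two taxa (missing entries excluded). This is the
#'   standard counting rule and is exact for unordered binary characters.
#' * `"oracle"` — a character is informative iff its minimum parsimony
#'   length varies across the full set of unrooted binary topologies under
#'   the given treatment (exhaustive scoring; requires >= 4 taxa). This is
#'   the defining criterion and can disagree with the pattern rule for
#'   ordered multistate characters.
#'
#' @param x A [char_matrix].
#' @param criterion `"pattern"` or `"oracle"`.
#' @param treatment Character treatment for the oracle criterion:
#'   `"ordered_multistate"` honours the matrix's ordered flags,
#'   `"unordered"` scores every character by Fitch.
#' @return A tibble with columns `character`, `ordered`, `binary`,
#'   `informative`.
#' @examples
#' classify_informative(sitophilus_matrix())
#' @export
classify_informative <- function(x, criterion = c("pattern", "oracle"),
                                 treatment = c("ordered_multistate", "unordered")) {
  stopifnot(inherits(x, "char_matrix"))
  criterion <- match.arg(criterion)
  treatment <- match.arg(treatment)
  maxs <- apply(x$states, 2, function(s) {
    if (all(is.na(s))) 0L else max(s, na.rm = TRUE)
  })
  binary <- maxs <= 1L
  if (criterion == "pattern") {
    inf <- apply(x$states, 2, function(s) {
      tab <- table(s[!is.na(s)])
      sum(tab >= 2) >= 2
    })
  } else {
    if (nrow(x$states) < 4) {
      stop("oracle criterion needs >= 4 taxa (no competing topologies)")
    }
    topo <- enum_topologies(taxa(x))
    L <- score_topologies(topo, x, treatment)  # n_topo x n_char
    inf <- apply(L, 2, function(v) max(v) > min(v))
  }
  tibble::tibble(
    character = colnames(x$states),
    ordered = effective_ordered(x, treatment),
    binary = unname(binary),
    informative = unname(inf)
  )
}

#' Count parsimony-informative characters
#'
#' Reports the pattern-rule informative count over all characters and over
#' the binary characters only; the two can legitimately differ when graded
#' multistate characters are present.
#'
#' @param x A [char_matrix].
#' @return A tibble with columns `set` and `n_informative`.
#' @export
count_informative <- function(x) {
  cl <- classify_informative(x, criterion = "pattern")
  tibble::tibble(
    set = c("all characters", "binary characters"),
    n_informative = c(sum(cl$informative), sum(cl$informative & cl$binary))
  )
}

effective_ordered <- function(x, treatment) {
  if (treatment == "unordered") rep(FALSE, ncol(x$states)) else x$ordered
}
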