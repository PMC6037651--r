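#' Chromosome morphology classes
#'
#' Closed set of centromere-position classes used throughout the package,
#' following the classical Levan nomenclature, plus the minute "dot-like"
#' class seen in some beetle Y chromosomes.
#'
#' @format Character vector of class labels.
#' @export
chromosome_classes <- c(
  "metacentric", "submetacentric", "subtelocentric", "telocentric", "dot-like"
)

#' Sex-chromosome systems
#'
#' Closed set of male sex-chromosome systems handled by the package: the
#' Coleopteran "parachute" Xyp bivalent and the derived neo-XY system.
#'
#' @format Character vector of system labels.
#' @export
sex_systems <- c("Xyp", "neo-XY")

# autosome count column names, in chromosome_classes order
auto_cols <- c(
  "auto_metacentric", "auto_submetacentric", "auto_subtelocentric",
  "auto_telocentric", "auto_dotlike"
)

karyotype_columns <- c(
  "species", "diploid_number", auto_cols, "x_class", "y_class", "sex_system",
  "b_min", "b_max", "sexpair_code", "cband_code", "dapi_code", "cma3_code",
  "nor_code", "extra_categories"
)

#' Construct a table of karyotype records
#'
#' A karyotype record describes one species' chromosome complement: diploid
#' number, autosome counts per morphology class, X and Y morphology, the
#' sex-chromosome system, the range of supernumerary (B) chromosomes, and
#' small-integer codes for banding/fluorochrome/NOR patterns and the ordinal
#' "sexual pair" character. `extra_categories` holds additional exhibited
#' morphology-count categories (as `"class:count"`, semicolon-separated) for
#' complements scored against more than one rearrangement product.
#'
#' @param species Character vector of species names (unique).
#' @param diploid_number Integer 2n per species (even, >= 2).
#' @param auto_metacentric,auto_submetacentric,auto_subtelocentric,auto_telocentric,auto_dotlike
#'   Autosome counts per morphology class; must sum to 2n - 2.
#' @param x_class,y_class Morphology class of the X and Y chromosome
#'   (one of [chromosome_classes]).
#' @param sex_system One of [sex_systems].
#' @param b_min,b_max Minimum/maximum number of B chromosomes observed.
#' @param sexpair_code,cband_code,dapi_code,cma3_code,nor_code Small opaque
#'   integer pattern codes (NA = unknown).
#' @param extra_categories Extra exhibited count categories, `""` if none.
#'
#' @return A tibble with one row per species, class `karyotype_tbl`.
#' @examples
#' karyotype_records(
#'   species = "Sitophilus oryzae", diploid_number = 22,
#'   auto_metacentric = 18, auto_submetacentric = 2,
#'   x_class = "metacentric", y_class = "metacentric", sex_system = "Xyp"
#' )
#' @export
karyotype_records <- function(species, diploid_number,
                              auto_metacentric = 0, auto_submetacentric = 0,
                              auto_subtelocentric = 0, auto_telocentric = 0,
                              auto_dotlike = 0,
                              x_class = "metacentric", y_class = "metacentric",
                              sex_system = "Xyp",
                              b_min = 0, b_max = 0,
                              sexpair_code = NA_integer_,
                              cband_code = NA_integer_, dapi_code = NA_integer_,
                              cma3_code = NA_integer_, nor_code = NA_integer_,
                              extra_categories = "") {
  out <- tibble::tibble(
    species = as.character(species),
    diploid_number = as.integer(diploid_number),
    auto_metacentric = as.integer(auto_metacentric),
    auto_submetacentric = as.integer(auto_submetacentric),
    auto_subtelocentric = as.integer(auto_subtelocentric),
    auto_telocentric = as.integer(auto_telocentric),
    auto_dotlike = as.integer(auto_dotlike),
    x_class = as.character(x_class),
    y_class = as.character(y_class),
    sex_system = as.character(sex_system),
    b_min = as.integer(b_min),
    b_max = as.integer(b_max),
    sexpair_code = as.integer(sexpair_code),
    cband_code = as.integer(cband_code),
    dapi_code = as.integer(dapi_code),
    cma3_code = as.integer(cma3_code),
    nor_code = as.integer(nor_code),
    extra_categories = as.character(extra_categories)
  )
  class(out) <- c("karyotype_tbl", class(out))
  out
}

#' Validate karyotype records
#'
#' Checks each record against the structural invariants of a karyotype
#' description: even diploid number >= 2, autosome class counts summing to
#' 2n - 2, non-negative counts, a valid B-chromosome range, and recognised
#' morphology classes and sex system. Violations are reported, never thrown.
#'
#' @param records A tibble of karyotype records (see [karyotype_records()]).
#' @return A tibble with columns `species`, `valid` (logical) and
#'   `violations` (one semicolon-separated string, `""` when valid).
#' @examples
#' recs <- sitophilus_karyotypes()
#' validate_karyotype(recs)
#' @export
validate_karyotype <- function(records) {
  stopifnot(is.data.frame(records))
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    v <- character(0)
    if (is.na(r$diploid_number) || r$diploid_number < 2) {
      v <- c(v, "diploid number must be >= 2")
    } else if (r$diploid_number %% 2 != 0) {
      v <- c(v, "diploid number odd")
    }
    counts <- unlist(r[auto_cols])
    if (anyNA(counts) || any(counts < 0)) {
      v <- c(v, "negative or missing autosome count")
    } else if (!is.na(r$diploid_number) &&
               sum(counts) != r$diploid_number - 2L) {
      v <- c(v, "count mismatch: autosome classes must sum to 2n - 2")
    }
    if (!r$x_class %in% chromosome_classes) v <- c(v, "unknown X class")
    if (!r$y_class %in% chromosome_classes) v <- c(v, "unknown Y class")
    if (!r$sex_system %in% sex_systems) v <- c(v, "unknown sex system")
    if (is.na(r$b_min) || is.na(r$b_max) || r$b_min < 0 || r$b_min > r$b_max) {
      v <- c(v, "invalid B-chromosome range")
    }
    tibble::tibble(
      species = r$species, valid = length(v) == 0L,
      violations = paste(v, collapse = "; ")
    )
  })
}

#' Meiotic formula of a karyotype
#'
#' Renders the haploid meioformula `"n=<(2n-2)/2> + <pair>"` where the sex
#' pair symbol depends on the record's sex-chromosome system and the sex
#' requested: females of an Xyp species render `XX`, males `Xyp`; the neo-XY
#' system renders `neo-XX` / `neo-XY`.
#'
#' @param records A tibble of valid karyotype records.
#' @param sex `"male"` or `"female"`.
#' @return A tibble with columns `species`, `sex`, `meioformula`.
#' @examples
#' meioformula(sitophilus_karyotypes(), sex = "male")
#' @export
meioformula <- function(records, sex = c("male", "female")) {
  sex <- match.arg(sex)
  chk <- validate_karyotype(records)
  if (!all(chk$valid)) {
    bad <- chk[!chk$valid, ]
    stop("invalid karyotype record(s): ",
         paste0(bad$species, " (", bad$violations, ")", collapse = "; "))
  }
  n_auto <- (records$diploid_number - 2L) %/% 2L
  pair <- ifelse(
    records$sex_system == "Xyp",
    if (sex == "male") "Xyp" else "XX",
    if (sex == "male") "neo-XY" else "neo-XX"
  )
  tibble::tibble(
    species = records$species, sex = sex,
    meioformula = paste0("n=", n_auto, " + ", pair)
  )
}

# female complement count of a morphology class: autosomes + two X copies
female_class_counts <- function(records) {
  m <- as.matrix(records[auto_cols])
  colnames(m) <- chromosome_classes
  for (i in seq_len(nrow(records))) {
    xc <- records$x_class[i]
    m[i, xc] <- m[i, xc] + 2L
  }
  m
}

#' Packaged karyotype records of the grain weevils and outgroup
#'
#' The cytogenetic descriptions of *Sitophilus granarius*, *S. linearis*,
#' *S. oryzae*, *S. zeamais* and the outgroup *Otiorhynchus bisulcatus*,
#' as used by the karyotype-feature coding scheme. The outgroup record is
#' only partially known from published feature scores; unrecoverable fields
#' (the ordinal sexual-pair code, the placement of two residual autosomes)
#' are missing or inferred, as documented in the package vignette.
#'
#' @return A `karyotype_tbl` tibble with five rows.
#' @export
sitophilus_karyotypes <- function() {
  path <- system.file("extdata", "sitophilus_karyotypes.csv",
                      package = "cytophylo", mustWork = TRUE)
  read_karyotypes(path)
}

#' Read / write karyotype records as CSV
#'
#' One row per species, columns as in [karyotype_records()]. Round-trips
#' exactly.
#'
#' @param path File path.
#' @return `read_karyotypes()` returns a `karyotype_tbl`;
#'   `write_karyotypes()` returns `path` invisibly.
#' @export
read_karyotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = "NA")
  missing_cols <- setdiff(karyotype_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("karyotype CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$extra_categories[is.na(df$extra_categories)] <- ""
  do.call(karyotype_records, as.list(df[karyotype_columns]))
}

#' @rdname read_karyotypes
#' @param records A tibble of karyotype records.
#' @export
write_karyotypes <- function(records, path) {
  utils::write.csv(as.data.frame(records)[karyotype_columns], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
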