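#' Discrete character matrix
#'
#' Container for a taxa-by-characters matrix of small integer states with
#' missing data, per-character ordered/unordered flags, and a designated
#' outgroup. This is the unit of input to parsimony search and bootstrap
#' resampling.
#'
#' @param states Integer matrix, taxa in rows (rownames = taxon names),
#'   characters in columns (colnames = character names); `NA` = missing.
#' @param ordered Logical vector, one flag per character; `TRUE` means the
#'   character is scored on a linear ladder (Sankoff cost `|i - j|`),
#'   `FALSE` means unordered (Fitch). Defaults to the multistate rule:
#'   characters whose observed maximum state is >= 2 are ordered.
#' @param outgroup Optional taxon name used for rooting.
#' @return An object of class `char_matrix`.
#' @examples
#' m <- rbind(A = c(0, 1), B = c(0, 1), C = c(1, 0), D = c(1, 0))
#' colnames(m) <- c("one", "two")
#' char_matrix(m, outgroup = "A")
#' @export
char_matrix <- function(states, ordered = NULL, outgroup = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) stop("states must have taxon rownames")
  if (anyDuplicated(rownames(states))) stop("duplicate taxon names")
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("char", seq_len(ncol(states)))
  }
  if (any(states < 0, na.rm = TRUE)) stop("states must be >= 0")
  if (is.null(ordered)) {
    maxs <- suppressWarnings(apply(states, 2, max, na.rm = TRUE))
    maxs[!is.finite(maxs)] <- 0L
    ordered <- maxs >= 2
  }
  stopifnot(length(ordered) == ncol(states))
  if (!is.null(outgroup) && !outgroup %in% rownames(states)) {
    stop("outgroup '", outgroup, "' is not among the taxa")
  }
  structure(
    list(states = states, ordered = as.logical(unname(ordered)),
         outgroup = outgroup),
    class = "char_matrix"
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", nrow(x$states), " taxa x ", ncol(x$states),
      " characters (", sum(x$ordered), " ordered)",
      if (!is.null(x$outgroup)) paste0(", outgroup: ", x$outgroup), "\n",
      sep = "")
  print(x$states)
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' Taxa of a character matrix
#' @param x A `char_matrix`.
#' @return Character vector of taxon names.
#' @export
taxa <- function(x) rownames(x$states)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a character matrix into long form
#'
#' @param x A `char_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `character`, `state`, `ordered`.
#' @export
tidy.char_matrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(rownames(x$states), times = ncol(x$states)),
    character = rep(colnames(x$states), each = nrow(x$states)),
    state = as.integer(x$states),
    ordered = rep(x$ordered, each = nrow(x$states))
  )
}

#' @export
glance.char_matrix <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x$states), n_characters = ncol(x$states),
    n_ordered = sum(x$ordered),
    n_missing = sum(is.na(x$states)),
    outgroup = x$outgroup %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write character matrices
#'
#' Two on-disk formats are supported and round-trip exactly:
#'
#' * `"csv"` — taxa in rows, characters in columns, `?` for missing; header
#'   metadata lines `# ordered: ...` (comma-separated 0/1 flags) and
#'   `# outgroup: ...` precede the table.
#' * `"nexus"` — a `DATA` block (`FORMAT SYMBOLS="0123456789" MISSING=?`)
#'   plus an `ASSUMPTIONS` block whose `TYPESET` line records which
#'   characters are ordered.
#'
#' @param path File path.
#' @param format `"csv"` or `"nexus"`; default guessed from the extension.
#' @return `read_character_matrix()` returns a `char_matrix`;
#'   `write_character_matrix()` returns `path` invisibly.
#' @export
read_character_matrix <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "nexus"))
  if (format == "csv") read_cm_csv(path) else read_cm_nexus(path)
}

#' @rdname read_character_matrix
#' @param x A `char_matrix`.
#' @export
write_character_matrix <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "nexus"))
  if (format == "csv") write_cm_csv(x, path) else write_cm_nexus(x, path)
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE)) "nexus" else "csv"
}

read_cm_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "taxon") stop("character CSV must start with a 'taxon' column")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon in ", path)
  states <- as.matrix(df[, -1, drop = FALSE])
  bad <- matrix(!grepl("^([0-9]+|\\?)$", states), nrow = nrow(states))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown state symbol '", states[bad][1], "' at row ", idx[1],
         ", column ", idx[2] + 1L, " of ", path)
  }
  states[states == "?"] <- NA
  storage.mode(states) <- "integer"
  rownames(states) <- df$taxon
  ordered <- outgroup <- NULL
  for (m in meta) {
    if (grepl("^#\\s*ordered:", m)) {
      ordered <- as.logical(as.integer(strsplit(sub("^#\\s*ordered:\\s*", "", m),
                                                ",")[[1]]))
    } else if (grepl("^#\\s*outgroup:", m)) {
      outgroup <- trimws(sub("^#\\s*outgroup:\\s*", "", m))
    }
  }
  char_matrix(states, ordered = ordered, outgroup = outgroup)
}

write_cm_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ordered: ",
                    paste(as.integer(x$ordered), collapse = ",")), con)
  if (!is.null(x$outgroup)) {
    writeLines(paste0("# outgroup: ", x$outgroup), con)
  }
  chr <- x$states
  mode(chr) <- "character"
  chr[is.na(chr)] <- "?"
  df <- data.frame(taxon = rownames(x$states), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
}

write_cm_nexus <- function(x, path) {
  states <- x$states
  sym <- apply(states, 1, function(r) {
    r <- as.character(r)
    r[is.na(r)] <- "?"
    paste(r, collapse = "")
  })
  pad <- max(nchar(rownames(states))) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                     nrow(states), ncol(states)), con)
  writeLines("  FORMAT SYMBOLS=\"0123456789\" MISSING=?;", con)
  writeLines("  MATRIX", con)
  for (i in seq_len(nrow(states))) {
    writeLines(sprintf("    %-*s%s", pad, rownames(states)[i], sym[i]), con)
  }
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN ASSUMPTIONS;", con)
  ord <- which(x$ordered)
  uno <- which(!x$ordered)
  parts <- c(
    if (length(ord)) paste0("ord: ", paste(ord, collapse = " ")),
    if (length(uno)) paste0("unord: ", paste(uno, collapse = " "))
  )
  writeLines(paste0("  TYPESET * default = ", paste(parts, collapse = ", "),
                    ";"), con)
  if (!is.null(x$outgroup)) {
    writeLines(paste0("  [outgroup = ", x$outgroup, "]"), con)
  }
  writeLines("END;", con)
}

read_cm_nexus <- function(path) {
  dat <- ape::read.nexus.data(path)
  states <- do.call(rbind, lapply(dat, function(v) {
    v[v == "?"] <- NA
    as.integer(v)
  }))
  rownames(states) <- names(dat)
  lines <- readLines(path)
  ts <- grep("TYPESET", lines, ignore.case = TRUE, value = TRUE)
  ordered <- rep(FALSE, ncol(states))
  if (length(ts) >= 1) {
    spec <- sub(".*=", "", sub(";.*$", "", ts[1]))
    for (grp in strsplit(spec, ",")[[1]]) {
      kv <- strsplit(trimws(grp), ":")[[1]]
      if (length(kv) != 2) next
      idx <- unlist(lapply(strsplit(trimws(kv[2]), "\\s+")[[1]], function(tok) {
        if (grepl("-", tok)) {
          ab <- as.integer(strsplit(tok, "-")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(tok)
      }))
      if (tolower(trimws(kv[1])) == "ord") ordered[idx] <- TRUE
    }
  }
  og <- grep("\\[outgroup *=", lines, value = TRUE)
  outgroup <- if (length(og)) {
    trimws(sub("\\].*$", "", sub(".*outgroup *= *", "", og[1])))
  } else NULL
  char_matrix(states, ordered = ordered, outgroup = outgroup)
}
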