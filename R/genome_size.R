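#' DNA mass to base-pair conversion constant
#'
#' Megabase pairs per picogram of double-stranded DNA (1 pg = 978 Mbp), the
#' standard C-value conversion; overridable wherever it is used.
#'
#' @export
MBP_PER_PG <- 978

#' Convert genome-size units
#'
#' @param value Positive numeric vector.
#' @param from `"pg"` (picograms) or `"mbp"` (megabase pairs).
#' @param mbp_per_pg Conversion constant (default [MBP_PER_PG]).
#' @return Converted numeric vector (pg -> Mbp multiplies, Mbp -> pg
#'   divides). Report-style rounding (Mbp to 1 decimal, pg to 4) is left to
#'   the caller; see [genome_size_report()].
#' @examples
#' convert_units(0.5533, from = "pg")  # 541.1274 Mbp
#' @export
convert_units <- function(value, from = c("pg", "mbp"),
                          mbp_per_pg = MBP_PER_PG) {
  from <- match.arg(from)
  stopifnot(all(value > 0))
  if (from == "pg") value * mbp_per_pg else value / mbp_per_pg
}

#' Locate 2C fluorescence peaks in a flow run
#'
#' Finds the modes of a Gaussian kernel density estimate of per-nucleus
#' fluorescence (Silverman's rule-of-thumb bandwidth on the log scale) and
#' summarises each peak from the events inside a fractional gating window
#' around its mode.
#'
#' @param run A data frame with a `fluorescence` column (one row per
#'   nucleus, all values > 0, at least 100 events), or a numeric vector.
#' @param n_peaks Number of peaks expected (1 or 2).
#' @param gate_width Fractional half-width of the gating window (default
#'   0.10: events within +/- 10% of the mode).
#' @param min_prominence Minimum density height of a mode, as a fraction of
#'   the highest mode (default 0.05), below which a mode is ignored.
#' @return A tibble with one row per peak, ascending in fluorescence:
#'   `peak`, `mode`, `mean_fluorescence`, `n_events`, `cv` (percent).
#' @examples
#' set.seed(1)
#' run <- data.frame(fluorescence = c(rnorm(500, 100, 2), rnorm(500, 234, 5)))
#' locate_2c_peaks(run, n_peaks = 2)
#' @export
locate_2c_peaks <- function(run, n_peaks = 2, gate_width = 0.10,
                            min_prominence = 0.05) {
  x <- if (is.data.frame(run)) run$fluorescence else as.numeric(run)
  if (is.null(x)) stop("run must have a 'fluorescence' column")
  if (length(x) < 100) stop("need at least 100 events")
  if (any(x <= 0)) stop("fluorescence values must be > 0")
  if (!n_peaks %in% c(1, 2)) stop("n_peaks must be 1 or 2")

  d <- stats::density(log(x), bw = "nrd0")
  y <- d$y
  m <- which(diff(sign(diff(y))) == -2) + 1L
  m <- m[y[m] >= min_prominence * max(y[m])]
  if (length(m) < n_peaks) {
    stop("unresolved peaks: found ", length(m), " mode(s), expected ",
         n_peaks)
  }
  m <- m[order(y[m], decreasing = TRUE)][seq_len(n_peaks)]
  modes <- sort(exp(d$x[m]))
  purrr::map_dfr(seq_along(modes), function(i) {
    g <- x[x >= modes[i] * (1 - gate_width) & x <= modes[i] * (1 + gate_width)]
    tibble::tibble(
      peak = i,
      mode = modes[i],
      mean_fluorescence = mean(g),
      n_events = length(g),
      cv = 100 * stats::sd(g) / mean(g)
    )
  })
}

#' Haploid genome size from a sample/standard peak pair
#'
#' The 1C DNA amount is the ratio of the mean 2C fluorescence of the sample
#' to that of the co-prepared internal standard, times the standard's known
#' 1C content (default 328 Mbp, the *Drosophila virilis* standard).
#'
#' @param sample_peak,standard_peak One-row tibbles from
#'   [locate_2c_peaks()], or bare positive numerics (mean fluorescence).
#' @param standard_1c_mbp 1C content of the internal standard, in Mbp.
#' @param mbp_per_pg Unit-conversion constant.
#' @return A one-row tibble with `c1_mbp`, `c1_pg` and the fluorescence
#'   ratio.
#' @examples
#' estimate_1c(234, 100)  # ratio 2.34 -> 767.5 Mbp
#' @export
estimate_1c <- function(sample_peak, standard_peak, standard_1c_mbp = 328,
                        mbp_per_pg = MBP_PER_PG) {
  s <- peak_mean(sample_peak)
  r <- peak_mean(standard_peak)
  if (!is.finite(s) || !is.finite(r) || s <= 0 || r <= 0) {
    stop("peak means must be positive")
  }
  c1 <- s / r * standard_1c_mbp
  tibble::tibble(ratio = s / r, c1_mbp = c1,
                 c1_pg = convert_units(c1, from = "mbp",
                                       mbp_per_pg = mbp_per_pg))
}

peak_mean <- function(p) {
  if (is.data.frame(p)) as.numeric(p$mean_fluorescence[1]) else as.numeric(p)[1]
}

#' Genome size from a blind two-population flow run
#'
#' Full per-individual pipeline: locate the two 2C peaks (sample and
#' internal standard co-prepared in one run, labels unknown), identify the
#' standard by the declared side, and convert the fluorescence ratio to a
#' 1C estimate.
#'
#' @param run A data frame with a `fluorescence` column; optional `species`,
#'   `sex`, `individual` columns are carried through.
#' @param standard_is `"lower"` or `"upper"`: which peak is the internal
#'   standard, declared from the expected sample/standard ratio (never
#'   guessed from peak order).
#' @param standard_1c_mbp 1C content of the standard in Mbp (default 328).
#' @param gate_width Gating window half-width (see [locate_2c_peaks()]).
#' @param mbp_per_pg Unit-conversion constant.
#' @return A one-row tibble: metadata columns, `ratio`, `c1_mbp`, `c1_pg`.
#' @export
flow_genome_size <- function(run, standard_is = c("lower", "upper"),
                             standard_1c_mbp = 328, gate_width = 0.10,
                             mbp_per_pg = MBP_PER_PG) {
  standard_is <- match.arg(standard_is)
  peaks <- locate_2c_peaks(run, n_peaks = 2, gate_width = gate_width)
  std <- if (standard_is == "lower") 1 else 2
  est <- estimate_1c(peaks[-std, ], peaks[std, ],
                     standard_1c_mbp = standard_1c_mbp,
                     mbp_per_pg = mbp_per_pg)
  meta <- tibble::tibble(
    species = meta_col(run, "species"),
    sex = meta_col(run, "sex"),
    individual = meta_col(run, "individual")
  )
  dplyr::bind_cols(meta, est)
}

meta_col <- function(run, col) {
  if (is.data.frame(run) && col %in% names(run)) {
    as.character(run[[col]][1])
  } else NA_character_
}

#' Group summary of genome-size estimates
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of 1C values per
#' group; SE is `NA` for singleton groups.
#'
#' @param estimates A data frame with a `c1_mbp` column (e.g. rows from
#'   [flow_genome_size()]).
#' @param ... Grouping columns (tidy-select), e.g. `species, sex`.
#' @param mbp_per_pg Unit-conversion constant for the pg summary.
#' @return A tibble with `n`, `mean_mbp`, `se_mbp`, `mean_pg`, `se_pg` per
#'   group.
#' @export
summarize_group <- function(estimates, ..., mbp_per_pg = MBP_PER_PG) {
  stopifnot(is.data.frame(estimates))
  if (nrow(estimates) < 1) stop("no estimates to summarize")
  estimates |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_mbp = mean(.data$c1_mbp),
      se_mbp = stats::sd(.data$c1_mbp) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_pg = .data$mean_mbp / mbp_per_pg,
      se_pg = .data$se_mbp / mbp_per_pg
    )
}

#' Partition male estimates into B-carrier groups
#'
#' Splits a set of 1C estimates at the largest gap in sorted order into a
#' lower ("without Bs") and upper ("with Bs") group; the split is accepted
#' only when the gap exceeds `min_gap_sd` pooled within-group standard
#' deviations (singleton groups contribute no degrees of freedom), otherwise
#' a single group is returned.
#'
#' @param estimates A data frame with a `c1_mbp` column, or a numeric
#'   vector of 1C values (>= 2 values).
#' @param min_gap_sd Gap acceptance multiplier (default 3).
#' @return The input rows with a `b_group` column (`"without_B"` /
#'   `"with_B"`, or `"all"` when no split is accepted).
#' @export
partition_b_carriers <- function(estimates, min_gap_sd = 3) {
  vec <- if (is.data.frame(estimates)) estimates$c1_mbp else as.numeric(estimates)
  if (length(vec) < 2) stop("need at least 2 estimates")
  ord <- order(vec)
  v <- vec[ord]
  gaps <- diff(v)
  k <- which.max(gaps)
  lower <- v[seq_len(k)]
  upper <- v[-seq_len(k)]
  ss <- function(g) if (length(g) > 1) (length(g) - 1) * stats::var(g) else 0
  df <- (length(lower) - 1) + (length(upper) - 1)
  pooled_sd <- if (df > 0) sqrt((ss(lower) + ss(upper)) / df) else 0
  split_ok <- gaps[k] > min_gap_sd * pooled_sd && gaps[k] > 0
  grp <- if (split_ok) {
    ifelse(vec <= v[k], "without_B", "with_B")
  } else {
    rep("all", length(vec))
  }
  if (is.data.frame(estimates)) {
    dplyr::mutate(tibble::as_tibble(estimates), b_group = grp)
  } else {
    tibble::tibble(c1_mbp = vec, b_group = grp)
  }
}

#' Report table of genome-size estimates
#'
#' Group summary laid out like a publication table: one row per group with
#' `pg ± SE (Mbp ± SE)` strings (pg to 4 decimals, Mbp to 1) and n.
#'
#' @param estimates A data frame of per-individual estimates with `c1_mbp`
#'   and grouping columns.
#' @param ... Grouping columns (tidy-select), default `species, sex`.
#' @param mbp_per_pg Unit-conversion constant.
#' @return A tibble with the grouping columns, `n`, `pg_se`, `mbp_se` and
#'   the numeric summary columns.
#' @export
genome_size_report <- function(estimates, ..., mbp_per_pg = MBP_PER_PG) {
  dots <- rlang::enquos(...)
  if (length(dots) == 0) {
    s <- summarize_group(estimates, .data$species, .data$sex,
                         mbp_per_pg = mbp_per_pg)
  } else {
    s <- summarize_group(estimates, !!!dots, mbp_per_pg = mbp_per_pg)
  }
  dplyr::mutate(
    s,
    pg_se = sprintf("%.4f ± %s", .data$mean_pg,
                    ifelse(is.na(.data$se_pg), "NA",
                           sprintf("%.4f", .data$se_pg))),
    mbp_se = sprintf("%.1f ± %s", .data$mean_mbp,
                     ifelse(is.na(.data$se_mbp), "NA",
                            sprintf("%.1f", .data$se_mbp)))
  )
}

#' Histogram of a flow run with located peaks
#'
#' @param object A data frame with a `fluorescence` column.
#' @param n_peaks Peaks to locate and mark.
#' @param ... Passed to [locate_2c_peaks()].
#' @return A ggplot object.
#' @export
plot_flow_run <- function(object, n_peaks = 2, ...) {
  peaks <- locate_2c_peaks(object, n_peaks = n_peaks, ...)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fluorescence)) +
    ggplot2::geom_histogram(bins = 120, fill = "grey70") +
    ggplot2::geom_vline(data = peaks,
                        ggplot2::aes(xintercept = .data$mean_fluorescence),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "fluorescence (instrument units)", y = "nuclei") +
    ggplot2::theme_minimal()
}
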