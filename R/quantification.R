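#' Root length at a day from its final length and relative length
#'
#' `Length_n = Length * (1 - RL)`: RL 0 gives the full final length, RL 1
#' gives 0 (the root has not yet initiated).
#'
#' @param final_length_mm root length at the last day, mm.
#' @param rl relative length in `[0, 1]` (vectorized).
#' @return length in mm.
#' @export
length_at_day <- function(final_length_mm, rl) {
  if (any(rl < 0 | rl > 1)) stopf("rl outside [0, 1]")
  if (any(final_length_mm < 0)) stopf("final length must be >= 0")
  final_length_mm * (1 - rl)
}

#' Per-root growth table
#'
#' Combines the fitted elongation parameters with the last-day vector into
#' the biology-facing summary: per root the final length (last-day polyline
#' arc length times voxel size), elongation start/end days, elongation rate,
#' and classification; and per (root, day) the denoised length obtained by
#' evaluating the fitted model curve (raw per-day relative lengths are kept
#' alongside for audit when `trajectories` is supplied).
#'
#' @param fits data frame from [fit_trajectories()].
#' @param vector_last_day the [rsa_vector()] at the last day.
#' @param days days to tabulate lengths at.
#' @param trajectories optional raw trajectory data frame from
#'   [build_trajectories()]; adds an `rl_raw`/`length_raw_mm` audit column.
#' @return an object of class `growth_table`: a list with `roots` (per-root
#'   data frame) and `lengths` (per root x day data frame).
#' @export
growth_table <- function(fits, vector_last_day, days, trajectories = NULL) {
  stopifnot(inherits(vector_last_day, "rsa_vector"))
  vx <- vector_last_day$voxel_size_mm
  final_mm <- vapply(fits$root_id, function(id) {
    r <- vector_last_day$roots[[id]]
    if (is.null(r)) stopf("root %s not present in the last-day vector", id)
    root_length_mm(r, vx)
  }, numeric(1))
  roots <- data.frame(root_id = fits$root_id,
                      final_length_mm = final_mm,
                      x1 = fits$x1, x2 = fits$x2, ythr = fits$ythr,
                      mse = fits$mse, classification = fits$classification)
  roots$elongation_rate_mm_day <- ifelse(
    roots$classification == "pre_existing", NA_real_,
    elongation_rate(roots$final_length_mm, roots$x1, roots$x2))
  lengths <- do.call(rbind, lapply(seq_len(nrow(roots)), function(i) {
    rl <- fitted_rl(roots[i, ], days)
    data.frame(root_id = roots$root_id[i], day = days,
               rl_fit = rl,
               length_mm = length_at_day(roots$final_length_mm[i], rl))
  }))
  if (!is.null(trajectories)) {
    key <- paste(lengths$root_id, lengths$day)
    tkey <- paste(trajectories$root_id, trajectories$day)
    lengths$rl_raw <- trajectories$rl[match(key, tkey)]
    lengths$length_raw_mm <- ifelse(
      is.na(lengths$rl_raw), NA_real_,
      length_at_day(lengths$length_mm * 0 +
                      roots$final_length_mm[match(lengths$root_id, roots$root_id)],
                    lengths$rl_raw))
  }
  rownames(lengths) <- NULL
  structure(list(roots = roots, lengths = lengths, days = days),
            class = "growth_table")
}

# Biological relative length of one growth-table row at the given days.
# The fitted ythr < 1 plateau models a *measurement* artifact (scores held
# high by an overlapping root near the base), not biology: before x1 the
# root is absent, so the reported curve caps RL at 1, keeping Length 0
# before x1 and the full length after x2.
fitted_rl <- function(root_row, days) {
  if (root_row$classification == "pre_existing") return(rep(0, length(days)))
  growth_model_curve(root_row$x1, root_row$x2, 1, days)
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("growth_table: %d roots x %d days\n", nrow(x$roots), length(x$days)))
  print(x$roots)
  invisible(x)
}

#' Root count per day
#'
#' A root is counted at a day when its fitted length at that day is greater
#' than zero; pre-existing roots (full length throughout) count on every
#' day.
#'
#' @param table a [growth_table()].
#' @param days days to count at; defaults to the table's days.
#' @return data frame with columns `day` and `count`.
#' @export
root_count_series <- function(table, days = table$days) {
  stopifnot(inherits(table, "growth_table"))
  counts <- vapply(days, function(d) {
    sum(vapply(seq_len(nrow(table$roots)), function(i) {
      rl <- fitted_rl(table$roots[i, ], d)
      length_at_day(table$roots$final_length_mm[i], rl) > 0
    }, logical(1)))
  }, numeric(1))
  data.frame(day = days, count = as.integer(counts))
}

#' Constant elongation rate of a root
#'
#' Under the piecewise-linear growth model a root elongates from 0 to its
#' final length between days `x1` and `x2`, so its (constant) rate is
#' `final_length / (x2 - x1)`.
#'
#' @param final_length_mm final root length, mm (vectorized).
#' @param x1,x2 elongation start and end days; requires `x2 > x1`.
#' @return rate in mm/day.
#' @export
elongation_rate <- function(final_length_mm, x1, x2) {
  if (any(!is.na(x1) & !is.na(x2) & x2 <= x1)) stopf("requires x2 > x1")
  final_length_mm / (x2 - x1)
}

#' Correlation between emergence day and elongation rate
#'
#' Two-sided Pearson correlation test of the elongation start day `x1`
#' against the per-root elongation rate, excluding pre-existing roots
#' (their rate is undefined).
#'
#' @param table a [growth_table()].
#' @return a list with `r`, `p_value`, `n`.
#' @export
emergence_rate_correlation <- function(table) {
  stopifnot(inherits(table, "growth_table"))
  keep <- table$roots$classification != "pre_existing"
  x <- table$roots$x1[keep]
  rate <- table$roots$elongation_rate_mm_day[keep]
  if (sum(keep) < 3L) stopf("need at least 3 non-pre-existing roots")
  if (sd(x) == 0 || sd(rate) == 0) {
    warnf("degenerate variance; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = sum(keep)))
  }
  ct <- cor.test(x, rate, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Reconstruct per-day root-system vectors from relative lengths
#'
#' Shortens the last-day vector for every earlier day: each root's polyline
#' is truncated from the tip so the retained arc length is
#' `(1 - RL) x total`, with the cut node linearly interpolated on its
#' segment. Roots with RL 1 are omitted for that day; the last day's output
#' is identical to the input vector.
#'
#' @param vector_last_day the [rsa_vector()] at the last day.
#' @param rl_source either a trajectory data frame (`root_id`, `day`, `rl`;
#'   raw backward-prediction output) or a [growth_table()] (fitted,
#'   denoised relative lengths).
#' @param days days to reconstruct; defaults to the days present in
#'   `rl_source`.
#' @return a named list of [rsa_vector()] objects, one per day.
#' @export
reconstruct_vectors <- function(vector_last_day, rl_source, days = NULL) {
  stopifnot(inherits(vector_last_day, "rsa_vector"))
  rl_df <- if (inherits(rl_source, "growth_table")) {
    data.frame(root_id = rl_source$lengths$root_id, day = rl_source$lengths$day,
               rl = rl_source$lengths$rl_fit)
  } else rl_source
  if (any(rl_df$rl < 0 | rl_df$rl > 1)) stopf("RL outside [0, 1]")
  if (is.null(days)) days <- sort(unique(rl_df$day))
  out <- lapply(days, function(d) {
    roots <- list()
    for (r in vector_last_day$roots) {
      rl <- rl_df$rl[rl_df$root_id == r$id & rl_df$day == d]
      if (length(rl) != 1L) next  # no RL for this root/day
      if (d == vector_last_day$day) rl <- 0
      cum <- polyline_arclength(r$nodes)
      kept <- polyline_truncate(r$nodes, (1 - rl) * cum[length(cum)])
      if (is.null(kept) || nrow(kept) < 2L) next
      roots[[r$id]] <- list(id = r$id, nodes = kept)
    }
    rsa_vector(roots, vector_last_day$voxel_size_mm, d)
  })
  names(out) <- as.character(days)
  out
}
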