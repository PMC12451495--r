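#' Per-cell percentile temperature threshold
#'
#' Computes, for every grid cell, the q-th percentile of daily temperature
#' over a baseline window. By default all baseline days are pooled; with
#' `calendar_window_days > 0` a day-of-year climatology is built instead,
#' pooling days within +/- that many calendar days of each day of year.
#' Percentiles use the linear-interpolation estimator
#' (`stats::quantile`, type 7).
#'
#' @param cube A [temperature_cube()].
#' @param q Percentile level in (0, 100); 90 for heat waves, 10 for cold
#'   spells.
#' @param baseline_window Length-2 `Date` vector (inclusive); must lie
#'   within the cube's dates.
#' @param min_days Minimum number of unmasked baseline days per cell; cells
#'   below this are masked with a warning.
#' @param calendar_window_days Half-width of the optional day-of-year
#'   pooling window; 0 pools everything.
#' @return An object of class `threshold_field` with `values` either an
#'   `nlon x nlat` matrix (pooled) or a `c(366, nlon, nlat)` array (per
#'   day-of-year).
#' @export
compute_percentile_threshold <- function(cube, q, baseline_window,
                                         min_days = 30L,
                                         calendar_window_days = 0L) {
  stopifnot(inherits(cube, "temperature_cube"), q > 0, q < 100)
  baseline_window <- as.Date(baseline_window)
  stopifnot(length(baseline_window) == 2L)
  sel <- cube$dates >= baseline_window[1] & cube$dates <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no days of the cube", call. = FALSE)
  if (baseline_window[1] < min(cube$dates) || baseline_window[2] > max(cube$dates))
    stop("baseline window extends beyond the cube's dates", call. = FALSE)
  nd <- dim_grid(cube$grid)
  sub <- cube$values[, , sel, drop = FALSE]

  if (calendar_window_days == 0L) {
    vals <- matrix(NA_real_, nd[1], nd[2])
    nmasked <- 0L
    for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
      v <- sub[i, j, ]
      v <- v[!is.na(v)]
      if (length(v) < min_days) nmasked <- nmasked + 1L
      else vals[i, j] <- stats::quantile(v, q / 100, names = FALSE, type = 7)
    }
    if (nmasked > 0L)
      warning(sprintf("%d cells with fewer than %d unmasked baseline days were masked",
                      nmasked, min_days), call. = FALSE)
  } else {
    doy <- as.integer(format(cube$dates[sel], "%j"))
    vals <- array(NA_real_, c(366L, nd[1], nd[2]))
    win <- lapply(1:366, function(d) {
      dd <- abs(doy - d)
      which(pmin(dd, 366L - dd) <= calendar_window_days)
    })
    nmasked <- 0L
    for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
      v <- sub[i, j, ]
      ok <- !is.na(v)
      if (sum(ok) < min_days) { nmasked <- nmasked + 1L; next }
      for (d in 1:366) {
        w <- v[win[[d]]]
        w <- w[!is.na(w)]
        if (length(w)) vals[d, i, j] <- stats::quantile(w, q / 100, names = FALSE, type = 7)
      }
    }
    if (nmasked > 0L)
      warning(sprintf("%d cells with fewer than %d unmasked baseline days were masked",
                      nmasked, min_days), call. = FALSE)
  }
  structure(list(grid = cube$grid, q = q, values = vals,
                 baseline_window = baseline_window,
                 calendar_window_days = as.integer(calendar_window_days),
                 estimator = "linear-interpolation (type 7)"),
            class = "threshold_field")
}

#' Detect threshold-exceedance runs in a daily series
#'
#' Finds maximal runs of consecutive days strictly beyond a threshold
#' (`above`: value > threshold; `below`: value < threshold) of length at
#' least `min_len`. Each maximal run is one event regardless of its length.
#' Missing days (`NA`) never exceed, so they terminate runs.
#'
#' @param series Numeric vector of daily values (gap-free calendar days).
#' @param threshold Scalar threshold, or a vector the same length as
#'   `series` (per-day climatological thresholds).
#' @param direction `"above"` or `"below"`.
#' @param min_len Minimum run length in days (default 6).
#' @return A data frame with columns `start` (1-based index of the first
#'   day) and `length` (run length in days); zero rows if no event.
#' @examples
#' x <- rep(0, 20); x[3:9] <- 10; x[12:16] <- 10
#' detect_runs(x, 5, "above", min_len = 6)  # one 7-day event at day 3
#' @export
detect_runs <- function(series, threshold, direction = c("above", "below"),
                        min_len = 6L) {
  direction <- match.arg(direction)
  stopifnot(min_len >= 1L, length(threshold) %in% c(1L, length(series)))
  exceed <- if (direction == "above") series > threshold else series < threshold
  exceed[is.na(exceed)] <- FALSE
  r <- rle(as.vector(exceed))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Monthly heat-wave / cold-spell event counts
#'
#' Applies [detect_runs()] to every cell of a daily temperature cube and
#' bins events by the calendar month of their start day (a run crossing a
#' month boundary counts once, in its start month).
#'
#' @param cube A [temperature_cube()].
#' @param thresholds A `threshold_field` from [compute_percentile_threshold()].
#' @param direction `"above"` (heat waves) or `"below"` (cold spells).
#' @param min_len Minimum run length in days.
#' @param count_rule `"maximal"` (default): one maximal run = one event;
#'   `"windows"`: a maximal run of length L counts `floor(L / min_len)`
#'   events, assigned to the start months of consecutive non-overlapping
#'   windows.
#' @param event_class Label for the output; defaults by direction.
#' @return An [event_counts()] object spanning every complete or partial
#'   calendar month of the cube.
#' @export
monthly_event_counts <- function(cube, thresholds,
                                 direction = c("above", "below"),
                                 min_len = 6L,
                                 count_rule = c("maximal", "windows"),
                                 event_class = NULL) {
  direction <- match.arg(direction)
  count_rule <- match.arg(count_rule)
  stopifnot(inherits(cube, "temperature_cube"), inherits(thresholds, "threshold_field"))
  if (!grids_identical(cube$grid, thresholds$grid))
    stop("cube and threshold grids differ", call. = FALSE)
  if (as.integer(max(cube$dates)) - as.integer(min(cube$dates)) + 1L < 28L)
    stop("date range shorter than one month", call. = FALSE)
  if (is.null(event_class))
    event_class <- if (direction == "above") "heat_wave" else "cold_spell"

  months <- seq(as.Date(format(min(cube$dates), "%Y-%m-01")),
                as.Date(format(max(cube$dates), "%Y-%m-01")), by = "month")
  midx <- month_index(months)
  day_month <- match(month_index(as.Date(format(cube$dates, "%Y-%m-01"))), midx)
  nd <- dim_grid(cube$grid)
  per_doy <- length(dim(thresholds$values)) == 3L
  doy <- if (per_doy) as.integer(format(cube$dates, "%j")) else NULL

  counts <- array(0L, c(nd[1], nd[2], length(months)))
  mask <- matrix(TRUE, nd[1], nd[2])
  for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    thr <- if (per_doy) thresholds$values[doy, i, j] else thresholds$values[i, j]
    if (all(is.na(thr))) { mask[i, j] <- FALSE; next }
    runs <- detect_runs(cube$values[i, j, ], thr, direction, min_len)
    if (nrow(runs) == 0L) next
    starts <- if (count_rule == "maximal") runs$start
      else unlist(lapply(seq_len(nrow(runs)), function(k) {
        nwin <- runs$length[k] %/% min_len
        runs$start[k] + (seq_len(nwin) - 1L) * min_len
      }))
    tab <- tabulate(day_month[starts], nbins = length(months))
    counts[i, j, ] <- counts[i, j, ] + tab
  }
  event_counts(cube$grid, months, counts, event_class, mask)
}

#' Monthly drought events from SPEI
#'
#' Marks a cell-month as one drought event where SPEI is strictly below the
#' cutoff (severe drought at the default -1.5). Missing SPEI values leave
#' the count 0; cells missing in every month are masked.
#'
#' @param spei A [spei_cube()].
#' @param cutoff Drought cutoff (strict `<`), default -1.5.
#' @return An [event_counts()] object with 0/1 monthly counts,
#'   `event_class = "drought"`.
#' @export
drought_event_mask <- function(spei, cutoff = -1.5) {
  stopifnot(inherits(spei, "spei_cube"), is.finite(cutoff))
  hit <- spei$values < cutoff
  hit[is.na(hit)] <- FALSE
  mask <- apply(!is.na(spei$values), c(1, 2), any)
  event_counts(spei$grid, spei$months, array(as.integer(hit), dim(spei$values)),
               "drought", mask)
}
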