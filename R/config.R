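#' Analysis configuration
#'
#' Collects every scalar constant of the exposure pipeline in one validated
#' object. Defaults are the study settings: 6-day run-length event
#' definition at the 90th (heat) / 10th (cold) temperature percentile,
#' severe drought at SPEI3 < -1.5, decades 1980-1989 (baseline) vs.
#' 2010-2019 (recent), hazard layers at the 80th percentile of the
#' difference-in-counts, species exposed above 50% range overlap, and 2
#' degree aggregation cells.
#'
#' @param run_length_days Minimum run length (days) for a heat wave / cold
#'   spell event.
#' @param heat_q,cold_q Percentile levels (0-100) for the daily temperature
#'   thresholds.
#' @param spei_cutoff Drought cutoff on the standardized SPEI3 scale; a
#'   month is a drought event where SPEI3 is strictly below this value.
#' @param baseline_decade,recent_decade Length-2 integer year ranges,
#'   non-overlapping.
#' @param layer_percentile Percentile (0-100) of the in-mask
#'   difference-in-counts used to binarize heat and drought layers.
#' @param exposure_cutoff Overlap proportion strictly above which a species
#'   is exposed.
#' @param aggregation_cell_degrees Cell size (degrees) of the summary grid.
#' @param count_rule `"maximal"`: one maximal run of length >=
#'   `run_length_days` is one event (default); `"windows"`: a maximal run of
#'   length L counts `floor(L / run_length_days)` events (non-overlapping
#'   windows).
#' @param calendar_window_days Half-width (days) of the calendar-day window
#'   for the percentile climatology; 0 (default) pools all baseline days.
#' @param cold_include_zero If `TRUE` the cold layer keeps cells with a zero
#'   change in counts; default keeps strictly positive increases only.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(run_length_days = 6L,
                            heat_q = 90, cold_q = 10,
                            spei_cutoff = -1.5,
                            baseline_decade = c(1980L, 1989L),
                            recent_decade = c(2010L, 2019L),
                            layer_percentile = 80,
                            exposure_cutoff = 0.5,
                            aggregation_cell_degrees = 2,
                            count_rule = c("maximal", "windows"),
                            calendar_window_days = 0L,
                            cold_include_zero = FALSE) {
  count_rule <- match.arg(count_rule)
  stopifnot(run_length_days >= 1L,
            heat_q > 0, heat_q < 100, cold_q > 0, cold_q < 100,
            is.finite(spei_cutoff),
            layer_percentile > 0, layer_percentile < 100,
            exposure_cutoff > 0, exposure_cutoff < 1,
            aggregation_cell_degrees > 0,
            calendar_window_days >= 0L,
            length(baseline_decade) == 2L, length(recent_decade) == 2L,
            baseline_decade[1] <= baseline_decade[2],
            recent_decade[1] <= recent_decade[2])
  if (baseline_decade[2] >= recent_decade[1] && recent_decade[2] >= baseline_decade[1])
    stop("baseline and recent decades must not overlap", call. = FALSE)
  structure(list(run_length_days = as.integer(run_length_days),
                 heat_q = heat_q, cold_q = cold_q,
                 spei_cutoff = spei_cutoff,
                 baseline_decade = as.integer(baseline_decade),
                 recent_decade = as.integer(recent_decade),
                 layer_percentile = layer_percentile,
                 exposure_cutoff = exposure_cutoff,
                 aggregation_cell_degrees = aggregation_cell_degrees,
                 count_rule = count_rule,
                 calendar_window_days = as.integer(calendar_window_days),
                 cold_include_zero = isTRUE(cold_include_zero)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}
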