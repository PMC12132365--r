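# Live-cell trace analysis: CDK2 activity classification, cell-cycle entry
# curves, reporter accumulation slopes, DNA-content saddle split.

#' Construct a trace set
#'
#' @param values Cells x frames numeric matrix (activity or intensity).
#' @param frame_interval_min Minutes between frames (> 0).
#' @param induction_frame Optional 1-based frame index of reporter
#'   induction.
#' @param mask Optional logical matrix marking missing frames (tracking
#'   gaps); masked frames are excluded from durations and fractions, never
#'   imputed.
#' @param meta Optional per-cell metadata data frame.
#' @return A `trace_set` object.
#' @export
trace_set <- function(values, frame_interval_min, induction_frame = NULL,
                      mask = NULL, meta = NULL) {
  values <- as.matrix(values)
  assert_that(is.numeric(frame_interval_min) && frame_interval_min > 0,
              "`frame_interval_min` must be positive")
  assert_that(nrow(values) > 0 && ncol(values) > 0, "empty trace matrix")
  if (!is.null(mask)) {
    assert_that(all(dim(mask) == dim(values)),
                "`mask` must match the trace matrix shape")
  }
  if (!is.null(induction_frame)) {
    assert_that(induction_frame >= 1 && induction_frame <= ncol(values),
                "`induction_frame` outside the trace window")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell_%04d", seq_len(nrow(values)))
  }
  structure(list(values = values,
                 frame_interval_min = frame_interval_min,
                 induction_frame = induction_frame,
                 mask = mask, meta = meta),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("trace_set:", nrow(x$values), "cells x", ncol(x$values),
      "frames @", x$frame_interval_min, "min/frame\n")
  invisible(x)
}

#' Read traces from CSV
#'
#' Accepts long format (`cell_id`, `frame`, `value`) or wide format (one
#' row per cell, one column per frame, first column the cell id).
#'
#' @param path CSV path.
#' @param frame_interval_min Minutes per frame.
#' @param format `"long"` or `"wide"`.
#' @param induction_frame Optional induction frame.
#' @return A `trace_set`.
#' @export
read_traces <- function(path, frame_interval_min, format = c("long",
                                                             "wide"),
                        induction_frame = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    assert_that(all(c("cell_id", "frame", "value") %in% names(df)),
                "long format needs columns cell_id, frame, value")
    cells <- unique(df$cell_id)
    frames <- sort(unique(df$frame))
    m <- matrix(NA_real_, length(cells), length(frames),
                dimnames = list(cells, NULL))
    m[cbind(match(df$cell_id, cells), match(df$frame, frames))] <-
      df$value
    mask <- is.na(m)
    trace_set(m, frame_interval_min, induction_frame,
              mask = if (any(mask)) mask else NULL)
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    trace_set(m, frame_interval_min, induction_frame)
  }
}

#' Cumulative CDK2-low duration
#'
#' Hours each cell spends below the activity threshold: the number of
#' frames with activity strictly below `threshold`, times the frame
#' interval. Masked frames are excluded from both the numerator and the
#' usable movie length.
#'
#' @param traces A `trace_set` of CDK2 activity.
#' @param threshold Activity threshold (default 0.8).
#' @return Named numeric vector of hours, with attribute `"movie_hours"`
#'   (per-cell usable movie length).
#' @export
cdk2_low_duration <- function(traces, threshold = 0.8) {
  assert_that(inherits(traces, "trace_set"), "need a trace_set")
  assert_that(threshold > 0, "`threshold` must be positive")
  v <- traces$values
  low <- v < threshold
  usable <- matrix(TRUE, nrow(v), ncol(v))
  if (!is.null(traces$mask)) {
    usable <- !traces$mask
    low[!usable] <- FALSE
  }
  hours_per_frame <- traces$frame_interval_min / 60
  dur <- rowSums(low) * hours_per_frame
  names(dur) <- rownames(v)
  attr(dur, "movie_hours") <- rowSums(usable) * hours_per_frame
  dur
}

#' Classify cell-cycle behavior from CDK2-low durations
#'
#' `fast_cycling` when the cumulative low time is at most `fast_max`
#' hours; `predicted_senescent` when it is at least `senescent_min` hours;
#' `slow_cycling` otherwise. Increasing a duration never moves a cell
#' toward `fast_cycling`.
#'
#' @param durations Hours per cell (from [cdk2_low_duration()]).
#' @param movie_hours Movie length in hours.
#' @param fast_max Upper bound for a fast call (default 12 h).
#' @param senescent_min Lower bound for a senescent call (default 0.95 x
#'   the movie length).
#' @return Data frame with `cell_id`, `cdk2_low_hours`, `category`.
#' @export
classify_cycle <- function(durations, movie_hours, fast_max = 12,
                           senescent_min = 0.95 * movie_hours) {
  assert_that(fast_max > 0 && fast_max < senescent_min &&
                senescent_min <= movie_hours,
              "need 0 < fast_max < senescent_min <= movie_hours")
  category <- ifelse(durations <= fast_max, "fast_cycling",
                     ifelse(durations >= senescent_min,
                            "predicted_senescent", "slow_cycling"))
  data.frame(cell_id = names(durations) %||%
               seq_along(durations),
             cdk2_low_hours = unname(durations),
             category = unname(category), stringsAsFactors = FALSE)
}

#' Cell-cycle entry fraction per frame
#'
#' Fraction of cells with activity strictly above the threshold at each
#' frame; masked frames drop out of both numerator and denominator.
#'
#' @param traces A `trace_set` of CDK2 activity.
#' @param threshold Activity threshold (default 0.8).
#' @return Numeric vector, one value in `[0, 1]` per frame.
#' @export
entry_fraction_curve <- function(traces, threshold = 0.8) {
  assert_that(inherits(traces, "trace_set"), "need a trace_set")
  v <- traces$values
  high <- v > threshold
  if (!is.null(traces$mask)) {
    high[traces$mask] <- NA
    colMeans(high, na.rm = TRUE)
  } else {
    colMeans(high)
  }
}

#' Reporter accumulation slope per cell
#'
#' Each trace is normalized to its pre-induction mean; an ordinary
#' least-squares line is fit over the frames of `fit_window`, and the
#' per-frame slope is converted to normalized units per hour. A zero-noise
#' linear trace is recovered exactly.
#'
#' @param traces A `trace_set` with `induction_frame` set.
#' @param fit_window Integer frame range (>= 3 frames) after induction.
#' @return Data frame with `cell_id`, `baseline`, `slope_per_frame`,
#'   `slope_per_hour`.
#' @export
reporter_slope <- function(traces, fit_window) {
  assert_that(inherits(traces, "trace_set"), "need a trace_set")
  assert_that(!is.null(traces$induction_frame),
              "trace_set has no induction_frame")
  fit_window <- sort(as.integer(fit_window))
  assert_that(length(fit_window) >= 3, "fit window shorter than 3 frames")
  assert_that(min(fit_window) > traces$induction_frame,
              "fit window must start after induction")
  assert_that(max(fit_window) <= ncol(traces$values),
              "fit window exceeds the trace length")
  v <- traces$values
  pre <- v[, seq_len(traces$induction_frame), drop = FALSE]
  baseline <- rowMeans(pre)
  assert_that(all(baseline > 0), "pre-induction mean <= 0 for some cells")
  norm <- v / baseline
  xs <- fit_window
  slopes <- apply(norm[, xs, drop = FALSE], 1, function(yy) {
    stats::cov(xs, yy) / stats::var(xs)
  })
  data.frame(cell_id = rownames(v), baseline = unname(baseline),
             slope_per_frame = unname(slopes),
             slope_per_hour = unname(slopes) * 60 /
               traces$frame_interval_min,
             stringsAsFactors = FALSE)
}

#' Split DNA content at the saddle between 2N and 4N
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's bandwidth by
#' default); the threshold is the density minimum between the two highest
#' modes; cells are labeled `2N` below and `4N` at or above it. Unimodal
#' input is flagged and not split.
#'
#' @param dna_content Positive per-cell values (>= 50 cells).
#' @param bw Optional bandwidth (default `stats::bw.nrd0`).
#' @param n_grid Density grid size.
#' @return List with `threshold` (`NA` when flagged), `labels` (`"2N"` /
#'   `"4N"`, or `NA`s when flagged), `flag` (`TRUE` when fewer than two
#'   modes), and `density`.
#' @export
dna_saddle_split <- function(dna_content, bw = NULL, n_grid = 512) {
  assert_that(length(dna_content) >= 50,
              "need at least 50 cells for a stable density")
  assert_that(all(dna_content > 0), "DNA content values must be positive")
  dens <- if (is.null(bw)) {
    stats::density(dna_content, n = n_grid)
  } else {
    stats::density(dna_content, bw = bw, n = n_grid)
  }
  y <- dens$y
  x <- dens$x
  # local maxima of the KDE
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) {
    return(list(threshold = NA_real_,
                labels = rep(NA_character_, length(dna_content)),
                flag = TRUE, density = dens))
  }
  top2 <- is_max[order(-y[is_max])][1:2]
  lo <- min(top2)
  hi <- max(top2)
  valley <- seq(lo, hi)
  threshold <- x[valley[which.min(y[valley])]]
  labels <- ifelse(dna_content < threshold, "2N", "4N")
  list(threshold = threshold, labels = labels, flag = FALSE,
       density = dens)
}
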