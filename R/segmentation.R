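# Gait-cycle segmentation: from raw bilateral pressure signals to
# per-foot cycles with stance landmarks (heel strike, first peak, valley,
# second peak, toe-off), and selection of the 50-cycle analysis window.

#' Weight-normalize a pressure recording
#'
#' Divides every channel by body weight so pressures are expressed as
#' fractions of body weight (%BW). Single application is enforced: the
#' pipeline normalizes exactly once.
#'
#' @param rec a `pressure_recording` in raw units.
#' @return The recording with `units = "bw"`.
#' @export
normalize_by_weight <- function(rec) {
  assert_that(inherits(rec, "pressure_recording"), "rec must be a pressure_recording")
  assert_that(rec$body_weight > 0, "body_weight must be positive")
  if (identical(rec$units, "bw")) {
    stopf("recording is already weight-normalized; normalize_by_weight() must be applied once")
  }
  rec$left <- rec$left / rec$body_weight
  rec$right <- rec$right / rec$body_weight
  rec$units <- "bw"
  rec
}

#' Total vertical ground reaction force of one foot
#'
#' @param rec a `pressure_recording`.
#' @param foot `"left"` or `"right"`.
#' @return Numeric vector of length T: elementwise sum of the foot's 8
#'   channels.
#' @export
total_vgrf <- function(rec, foot = c("left", "right")) {
  foot <- match.arg(foot)
  rowSums(rec[[foot]])
}

# Local maxima indices of x within [from, to], plateaus resolved to their
# earliest sample.
local_maxima <- function(x, from, to) {
  seg <- x[from:to]
  n <- length(seg)
  if (n < 3) return(integer(0))
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (seg[i] > seg[i - 1]) {
      j <- i
      while (j < n && seg[j + 1] == seg[j]) j <- j + 1
      if (j < n && seg[j + 1] < seg[j]) out <- c(out, i)
    }
  }
  out + from - 1L
}

#' Detect gait cycles from a total-VGRF series
#'
#' Heel strike is the first sample of each sustained upward crossing of
#' the detection threshold; toe-off is the first subsequent sample that
#' falls back below it; the cycle ends at the next heel strike. Within
#' each stance, the two largest local maxima of total pressure (in
#' temporal order) give the two VGRF peaks and the minimum between them
#' the valley. Stances with fewer than two local maxima are excluded with
#' a warning (the bimodal pattern is assumed); the trailing incomplete
#' cycle is discarded.
#'
#' @param total numeric total-VGRF series (length >= 3).
#' @param threshold detection threshold in the series' units; defaults to
#'   5% of the series maximum.
#' @param min_rise_samples hysteresis: the rise must persist at least
#'   this many samples (default 2) to count as a heel strike.
#' @return List of gait cycles, each a list with 1-based sample indices
#'   `heel_strike`, `peak1`, `valley`, `peak2`, `toe_off`, `cycle_end`
#'   (`cycle_end` = next heel strike; the cycle span is
#'   `[heel_strike, cycle_end)`). The threshold used is attached as
#'   attribute `threshold` and all detected heel-strike rise indices
#'   (including the trailing incomplete cycle's) as attribute
#'   `heel_strikes`.
#' @export
detect_cycles <- function(total, threshold = NULL, min_rise_samples = 2) {
  assert_that(length(total) >= 3, "series too short for segmentation")
  threshold <- threshold %||% (0.05 * max(total))
  above <- total >= threshold
  n <- length(total)

  rises <- integer(0)
  i <- 2L
  while (i <= n - min_rise_samples + 1L) {
    if (!above[i - 1] && all(above[i:(i + min_rise_samples - 1L)])) {
      rises <- c(rises, i)
      i <- i + 1L
      while (i <= n && above[i]) i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(rises)) stopf("no gait detected: the series never crosses the threshold")

  cycles <- list()
  n_unimodal <- 0L
  for (k in seq_along(rises)) {
    hs <- rises[k]
    if (k == length(rises)) break  # trailing incomplete cycle
    cycle_end <- rises[k + 1]
    below <- which(!above[hs:(cycle_end - 1L)])
    if (!length(below)) next  # no toe-off before next strike
    toe_off <- hs + below[1] - 1L
    peaks <- local_maxima(total, hs, toe_off - 1L)
    if (length(peaks) < 2) {
      n_unimodal <- n_unimodal + 1L
      next
    }
    # two largest maxima; ties broken to the earlier sample; temporal order
    ord <- order(-total[peaks], peaks)
    two <- sort(peaks[ord[1:2]])
    valley <- two[1] + which.min(total[two[1]:two[2]]) - 1L
    cycles[[length(cycles) + 1L]] <- list(
      heel_strike = hs, peak1 = two[1], valley = valley, peak2 = two[2],
      toe_off = toe_off, cycle_end = cycle_end
    )
  }
  if (n_unimodal > 0) {
    warning(sprintf("%d cycle(s) without a bimodal stance excluded", n_unimodal),
            call. = FALSE)
  }
  attr(cycles, "threshold") <- threshold
  attr(cycles, "heel_strikes") <- rises
  cycles
}

#' Select the 50-cycle analysis window with left/right adjacency
#'
#' Drops the first `n_skip` (default 2) starting steps on each foot, then
#' pairs each subsequent left cycle with the right cycle whose heel
#' strike falls within the left cycle span (or whose stance overlaps it),
#' keeping the first `n_keep` (default 50) adjacent pairs.
#'
#' @param cycles_left,cycles_right cycle lists from [detect_cycles()].
#' @param n_keep number of cycle pairs to keep (default 50).
#' @param n_skip starting steps to exclude per foot (default 2).
#' @return An object of class `cycle_window`: list with `pairs` (each a
#'   list with `left` and `right` cycles) and `n`.
#' @export
select_window <- function(cycles_left, cycles_right, n_keep = 50, n_skip = 2) {
  need <- n_keep + n_skip
  for (side in list(list("left", cycles_left), list("right", cycles_right))) {
    cnt <- length(side[[2]])
    if (cnt < need) {
      stopf("insufficient cycles (%d < %d) on %s foot", cnt, need, side[[1]])
    }
  }
  lefts <- cycles_left[(n_skip + 1):length(cycles_left)]
  rights <- cycles_right[(n_skip + 1):length(cycles_right)]

  pairs <- list()
  j <- 1L
  for (lc in lefts) {
    # first right heel strike at or after this left heel strike
    while (j <= length(rights) && rights[[j]]$heel_strike < lc$heel_strike) j <- j + 1L
    if (j > length(rights)) break
    rc <- rights[[j]]
    adjacent <- rc$heel_strike < lc$cycle_end ||
      max(lc$heel_strike, rc$heel_strike) < min(lc$toe_off, rc$toe_off)
    if (adjacent) {
      pairs[[length(pairs) + 1L]] <- list(left = lc, right = rc)
      j <- j + 1L
      if (length(pairs) == n_keep) break
    }
  }
  if (length(pairs) < n_keep) {
    stopf("insufficient adjacent cycle pairs (%d < %d)", length(pairs), n_keep)
  }
  structure(list(pairs = pairs, n = n_keep), class = "cycle_window")
}

#' Segment a recording into its analysis window
#'
#' Convenience wrapper: total VGRF per foot, cycle detection with a
#' shared threshold, and 50-cycle window selection.
#'
#' @param rec a weight-normalized `pressure_recording`.
#' @param threshold detection threshold in %BW; defaults to 5% of the
#'   recording's maximum total VGRF (over both feet).
#' @inheritParams select_window
#' @return A `cycle_window` with the detection threshold attached as
#'   attribute `threshold`.
#' @export
segment_recording <- function(rec, threshold = NULL, n_keep = 50, n_skip = 2) {
  tl <- total_vgrf(rec, "left")
  tr <- total_vgrf(rec, "right")
  threshold <- threshold %||% (0.05 * max(c(tl, tr)))
  win <- select_window(detect_cycles(tl, threshold), detect_cycles(tr, threshold),
                       n_keep = n_keep, n_skip = n_skip)
  attr(win, "threshold") <- threshold
  win
}
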