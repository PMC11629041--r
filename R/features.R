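# Feature extraction: 54 single-foot features per foot + 2 bipedal
# temporal features per gait cycle, aggregated over the 50-cycle window,
# then expanded with symmetry-index, cycle-variability (STD), and
# weak-foot features into the 380-gait-feature + 4-physical-characteristic
# participant vector.

sensor_ids <- 1:8
region_defs <- list("1-4" = 1:4, "5-6" = 5:6, "7-8" = 7:8)

# Canonical foot-agnostic names of the 54 single-foot features, in the
# order they appear in the feature inventory.
base_feature_names <- function() {
  c(
    paste0(sensor_ids, "_PPP"),
    paste0(names(region_defs), "_PPP"),
    "peak1", "peak2", "4/2_PPP", "8/7_PPP",
    as.vector(rbind(paste0(sensor_ids, "_MaxPG"), paste0(sensor_ids, "_MinPG"))),
    as.vector(rbind(paste0(names(region_defs), "_MaxPG"),
                    paste0(names(region_defs), "_MinPG"))),
    "loadr", "unloadr", "valleyPG",
    "t_st/sw", "t_T", "t_st/T", "t_t1/T", "t_t2/T",
    "PTI_1", "PTI_st",
    "xcop_mean", "xcop_std", "ycop_mean", "ycop_std",
    "cop_len", "cop_MRD", "cop_SRD"
  )
}

# Foot-prefixed feature name; the PTI features keep their conventional
# no-underscore prefix (LPTI_1, RPTI_st).
foot_feature_names <- function(foot = c("L", "R"), base = base_feature_names()) {
  foot <- match.arg(foot)
  ifelse(startsWith(base, "PTI"), paste0(foot, base), paste0(foot, "_", base))
}

bipedal_feature_names <- function() c("t_single_support", "t_double_support")

#' Canonical participant feature names
#'
#' The 380 gait feature names (108 single-foot cycle means, 2 bipedal
#' temporal features, 54 symmetry indices, 108 cycle-to-cycle SDs, 108
#' weak-foot features) followed by the 4 physical characteristics.
#'
#' @return Character vector of length 384.
#' @export
participant_feature_names <- function() {
  base <- base_feature_names()
  c(
    foot_feature_names("L"), foot_feature_names("R"),
    bipedal_feature_names(),
    paste0("SI_", base),
    paste0(foot_feature_names("L"), "_STD"), paste0(foot_feature_names("R"), "_STD"),
    paste0("W_", base), paste0("W_", base, "_STD"),
    c("age", "height", "weight", "bmi")
  )
}

#' Machine-readable feature dictionary
#'
#' @return A data.frame with columns `name`, `group`, and `units` for all
#'   384 participant-level features.
#' @export
feature_dictionary <- function() {
  base <- base_feature_names()
  base_group <- function(b) {
    if (grepl("PPP$|^peak", b)) "PPP"
    else if (grepl("PG$|loadr$", b)) "PG"
    else if (startsWith(b, "t_")) "temporal"
    else if (startsWith(b, "PTI")) "PTI"
    else "COP"
  }
  base_units <- function(b) {
    switch(base_group(b),
           PPP = if (grepl("/", b)) "unitless" else "%BW",
           PG = "%BW/s",
           temporal = if (b == "t_T") "s" else "unitless",
           PTI = "%BW*s",
           COP = if (b == "cop_len" || grepl("RD$", b)) "normalized length"
                 else "normalized coordinate")
  }
  groups <- vapply(base, base_group, "")
  units <- vapply(base, base_units, "")
  rbind(
    data.frame(name = foot_feature_names("L"), group = groups, units = units),
    data.frame(name = foot_feature_names("R"), group = groups, units = units),
    data.frame(name = bipedal_feature_names(), group = "temporal", units = "s"),
    data.frame(name = paste0("SI_", base), group = "SI", units = "%"),
    data.frame(name = paste0(foot_feature_names("L"), "_STD"), group = "STD", units = units),
    data.frame(name = paste0(foot_feature_names("R"), "_STD"), group = "STD", units = units),
    data.frame(name = paste0("W_", base), group = "weak", units = units),
    data.frame(name = paste0("W_", base, "_STD"), group = "weak", units = units),
    data.frame(name = c("age", "height", "weight", "bmi"), group = "physical",
               units = c("years", "cm", "kg", "kg/m2")),
    make.row.names = FALSE
  )
}

#' Extract one cycle's channel slice with relative landmarks
#'
#' @param rec a weight-normalized `pressure_recording`.
#' @param cycle a cycle from [detect_cycles()] (absolute indices).
#' @param foot `"left"` or `"right"`.
#' @return A `gait_cycle` list: `mat` (cycle samples x 8, %BW),
#'   `landmarks` (1-based indices relative to the slice), `dt`.
#' @export
cycle_slice <- function(rec, cycle, foot = c("left", "right")) {
  foot <- match.arg(foot)
  hs <- cycle$heel_strike
  idx <- hs:(cycle$cycle_end - 1L)
  lm <- lapply(cycle[c("heel_strike", "peak1", "valley", "peak2", "toe_off", "cycle_end")],
               function(i) i - hs + 1L)
  structure(list(mat = rec[[foot]][idx, , drop = FALSE], landmarks = lm,
                 dt = 1 / rec$sampling_rate), class = "gait_cycle")
}

safe_ratio <- function(num, den) if (!is.finite(den) || den == 0) NA_real_ else num / den

#' Peak plantar pressure features (15 per foot)
#'
#' Per-sensor maxima (8), maxima of the summed forefoot/midfoot/heel
#' regional series (3), the two total-VGRF peaks (2), and the
#' lateral/medial peak-pressure ratios of forefoot (4/2) and heel (8/7).
#' Undefined ratios (zero denominator) are flagged as `NA`.
#'
#' @param cycle a `gait_cycle` (see [cycle_slice()]).
#' @return Named numeric vector of 15 values (foot-agnostic names).
#' @export
ppp_features <- function(cycle) {
  mat <- cycle$mat
  lm <- cycle$landmarks
  total <- rowSums(mat)
  sensor_max <- apply(mat, 2, max)
  regional <- vapply(region_defs, function(cols) max(rowSums(mat[, cols, drop = FALSE])), 0)
  out <- c(sensor_max, regional,
           total[lm$peak1], total[lm$peak2],
           safe_ratio(sensor_max[4], sensor_max[2]),
           safe_ratio(sensor_max[8], sensor_max[7]))
  names(out) <- c(paste0(sensor_ids, "_PPP"), paste0(names(region_defs), "_PPP"),
                  "peak1", "peak2", "4/2_PPP", "8/7_PPP")
  out
}

#' Pressure gradient features (25 per foot)
#'
#' Max/min discrete time derivative per sensor (16) and per summed
#' regional series (6); the loading rate (total VGRF rise from heel
#' strike to the first peak), the off-loading rate (fall from the second
#' peak to toe-off, stored signed), and the valley gradient sum
#' (sum of |dP/dt| between the two peaks of the total curve).
#'
#' @param cycle a `gait_cycle`.
#' @return Named numeric vector of 25 values.
#' @export
pg_features <- function(cycle) {
  mat <- cycle$mat
  lm <- cycle$landmarks
  dt <- cycle$dt
  assert_that(nrow(mat) >= 2, "cycle shorter than 2 samples")
  total <- rowSums(mat)
  d <- diff(mat) / dt
  per_sensor <- as.vector(rbind(apply(d, 2, max), apply(d, 2, min)))
  per_region <- unlist(lapply(region_defs, function(cols) {
    dr <- diff(rowSums(mat[, cols, drop = FALSE])) / dt
    c(max(dr), min(dr))
  }), use.names = FALSE)
  loadr <- if (lm$peak1 > lm$heel_strike) {
    (total[lm$peak1] - total[lm$heel_strike]) / ((lm$peak1 - lm$heel_strike) * dt)
  } else NA_real_
  unloadr <- if (lm$toe_off > lm$peak2) {
    (total[lm$toe_off] - total[lm$peak2]) / ((lm$toe_off - lm$peak2) * dt)
  } else NA_real_
  valley_pg <- sum(abs(diff(total[lm$peak1:lm$peak2]))) / dt
  out <- c(per_sensor, per_region, loadr, unloadr, valley_pg)
  names(out) <- c(
    as.vector(rbind(paste0(sensor_ids, "_MaxPG"), paste0(sensor_ids, "_MinPG"))),
    as.vector(rbind(paste0(names(region_defs), "_MaxPG"),
                    paste0(names(region_defs), "_MinPG"))),
    "loadr", "unloadr", "valleyPG"
  )
  out
}

#' Single-foot temporal features (5 per foot)
#'
#' Stance/swing time ratio, gait cycle time T, stance fraction of T, and
#' the cycle-time fractions of the two VGRF peaks (times from heel
#' strike). Zero swing duration flags the stance/swing ratio as `NA`.
#'
#' @param cycle a `gait_cycle`.
#' @return Named numeric vector of 5 values.
#' @export
temporal_features <- function(cycle) {
  lm <- cycle$landmarks
  dt <- cycle$dt
  Tt <- (lm$cycle_end - lm$heel_strike) * dt
  st <- (lm$toe_off - lm$heel_strike) * dt
  sw <- Tt - st
  out <- c(if (sw > 0) st / sw else NA_real_, Tt, st / Tt,
           (lm$peak1 - lm$heel_strike) * dt / Tt,
           (lm$peak2 - lm$heel_strike) * dt / Tt)
  names(out) <- c("t_st/sw", "t_T", "t_st/T", "t_t1/T", "t_t2/T")
  out
}

#' Bipedal support times over one cycle span
#'
#' Double support: both feet's total VGRF above the detection threshold;
#' single support: exactly one foot above it. Durations in seconds
#' within the half-open span `[from, to)`.
#'
#' @param total_left,total_right full-length total-VGRF series.
#' @param from,to 1-based sample bounds of the anchor cycle span.
#' @param threshold detection threshold (same units as the series).
#' @param dt sampling interval in seconds.
#' @return Named numeric vector `t_single_support`, `t_double_support`.
#' @export
bipedal_support_times <- function(total_left, total_right, from, to, threshold,
                                  dt = DT) {
  idx <- from:(to - 1L)
  la <- total_left[idx] >= threshold
  ra <- total_right[idx] >= threshold
  out <- c(sum(xor(la, ra)) * dt, sum(la & ra) * dt)
  names(out) <- bipedal_feature_names()
  out
}

#' Pressure-time integral features (2 per foot)
#'
#' Trapezoidal integral of total VGRF from heel strike to the first peak
#' (PTI_1) and over the stance phase (PTI_st), in %BW*s.
#'
#' @param cycle a `gait_cycle`.
#' @return Named numeric vector of 2 values.
#' @export
pti_features <- function(cycle) {
  lm <- cycle$landmarks
  total <- rowSums(cycle$mat)
  out <- c(trapz_dt(total[lm$heel_strike:lm$peak1], cycle$dt),
           trapz_dt(total[lm$heel_strike:lm$toe_off], cycle$dt))
  names(out) <- c("PTI_1", "PTI_st")
  out
}

#' Center-of-pressure trajectory features (7 per foot)
#'
#' The per-sample COP is the pressure-weighted mean of the normalized
#' sensor coordinates, computed over stance samples whose total pressure
#' exceeds the detection threshold. Features: mean and SD of the
#' medial-lateral (x) and anterior-posterior (y) coordinates, trajectory
#' length (sum of consecutive Euclidean distances), and the mean (MRD)
#' and SD (SRD) of the resultant distances from each COP point to the
#' stance-mean COP point.
#'
#' @param cycle a `gait_cycle`.
#' @param layout a [sensor_layout()].
#' @param threshold stance detection threshold in %BW.
#' @return Named numeric vector of 7 values (`NA` when no stance sample
#'   exceeds the threshold).
#' @export
cop_features <- function(cycle, layout, threshold) {
  lm <- cycle$landmarks
  nm <- c("xcop_mean", "xcop_std", "ycop_mean", "ycop_std",
          "cop_len", "cop_MRD", "cop_SRD")
  stance <- lm$heel_strike:(lm$toe_off - 1L)
  mat <- cycle$mat[stance, , drop = FALSE]
  total <- rowSums(mat)
  keep <- total > threshold
  if (!any(keep)) {
    out <- rep(NA_real_, 7); names(out) <- nm
    return(out)
  }
  mat <- mat[keep, , drop = FALSE]
  total <- total[keep]
  px <- as.vector(mat %*% layout$coords[, 1]) / total
  py <- as.vector(mat %*% layout$coords[, 2]) / total
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  rd <- sqrt((px - mean(px))^2 + (py - mean(py))^2)
  out <- c(mean(px), sd0(px), mean(py), sd0(py),
           sum(sqrt(diff(px)^2 + diff(py)^2)), mean(rd), sd0(rd))
  names(out) <- nm
  out
}

#' All 110 per-cycle features for one left/right cycle pair
#'
#' @param rec a weight-normalized `pressure_recording`.
#' @param pair one element of a `cycle_window`'s `pairs`.
#' @param threshold detection threshold in %BW.
#' @return Named numeric vector: 54 left + 54 right + 2 bipedal.
#' @export
cycle_pair_features <- function(rec, pair, threshold) {
  per_foot <- function(foot, prefix) {
    cyc <- cycle_slice(rec, pair[[foot]], foot)
    v <- c(ppp_features(cyc), pg_features(cyc), temporal_features(cyc),
           pti_features(cyc), cop_features(cyc, rec$layout, threshold))
    names(v) <- foot_feature_names(prefix, names(v))
    v
  }
  bi <- bipedal_support_times(total_vgrf(rec, "left"), total_vgrf(rec, "right"),
                              pair$left$heel_strike, pair$left$cycle_end,
                              threshold, dt = 1 / rec$sampling_rate)
  c(per_foot("left", "L"), per_foot("right", "R"), bi)
}

#' Aggregate per-cycle features over the analysis window
#'
#' Arithmetic mean of all 110 per-cycle features and sample SD (n-1) of
#' the 108 single-foot features, named with suffix `_STD`. Missing
#' per-cycle values are excluded; a feature missing in every cycle stays
#' `NA` at the participant level.
#'
#' @param cycle_table numeric matrix (cycles x 110) from
#'   [cycle_pair_features()].
#' @return List with `means` (110 values) and `stds` (108 values).
#' @export
aggregate_cycles <- function(cycle_table) {
  means <- apply(cycle_table, 2, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  single <- setdiff(colnames(cycle_table), bipedal_feature_names())
  stds <- apply(cycle_table[, single, drop = FALSE], 2, function(x) {
    if (sum(!is.na(x)) < 2) NA_real_ else stats::sd(x, na.rm = TRUE)
  })
  names(stds) <- paste0(single, "_STD")
  list(means = means, stds = stds)
}

#' Symmetry index
#'
#' Robinson symmetry index between corresponding left and right foot
#' features: `SI = |L - R| / (0.5 (L + R)) * 100` (percent). Symmetric in
#' its arguments and zero for a perfectly symmetric gait; flagged `NA`
#' when `L + R = 0`.
#'
#' @param L_f,R_f numeric vectors of corresponding left/right features.
#' @return Numeric vector of symmetry indices.
#' @export
symmetry_index <- function(L_f, R_f) {
  s <- 0.5 * (L_f + R_f)
  out <- 100 * abs(L_f - R_f) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' Weak-foot features
#'
#' The weak foot is the one with larger anterior-posterior COP
#' variability (cycle-averaged `ycop_std`); ties select the left foot.
#' Its 54 cycle means and 54 SDs are copied with the `W_` prefix.
#'
#' @param means named vector of the 110 cycle means.
#' @param stds named vector of the 108 `_STD` features.
#' @return List with `weak_foot` ("left"/"right") and `features`
#'   (108 named values).
#' @export
weak_foot_features <- function(means, stds) {
  weak <- if (means[["R_ycop_std"]] > means[["L_ycop_std"]]) "R" else "L"
  base <- base_feature_names()
  src <- foot_feature_names(weak, base)
  out <- c(means[src], stds[paste0(src, "_STD")])
  names(out) <- c(paste0("W_", base), paste0("W_", base, "_STD"))
  list(weak_foot = if (weak == "L") "left" else "right", features = out)
}

#' Assemble the participant feature vector
#'
#' Combines cycle means, bipedal features, symmetry indices, STD and
#' weak-foot features with the physical characteristics into the
#' canonical 384-entry vector, verifying the group counts
#' (PPP 30, PG 50, temporal 12, PTI 4, COP 14, SI 54, STD 108, weak 108,
#' physical 4).
#'
#' @param means,stds output of [aggregate_cycles()].
#' @param physical named list or vector with `age`, `height`, `weight`,
#'   `bmi`.
#' @return Named numeric vector of length 384 with attribute `weak_foot`.
#' @export
assemble_features <- function(means, stds, physical) {
  base <- base_feature_names()
  si <- symmetry_index(means[foot_feature_names("L", base)],
                       means[foot_feature_names("R", base)])
  names(si) <- paste0("SI_", base)
  weak <- weak_foot_features(means, stds)
  phys <- c(age = physical[["age"]], height = physical[["height"]],
            weight = physical[["weight"]], bmi = physical[["bmi"]])
  out <- c(means, si, stds, weak$features, phys)
  canonical <- participant_feature_names()
  if (!setequal(names(out), canonical) || length(out) != length(canonical)) {
    stopf("internal consistency error: feature inventory mismatch (%d != %d)",
          length(out), length(canonical))
  }
  out <- out[canonical]
  attr(out, "weak_foot") <- weak$weak_foot
  out
}

#' Extract the full feature vector for one participant
#'
#' Weight normalization, segmentation into the 50-cycle window, per-cycle
#' feature extraction, aggregation, and feature expansion.
#'
#' @param rec a `pressure_recording` in raw units.
#' @param physical named list/vector with `age`, `height`, `weight`, `bmi`.
#' @param threshold segmentation threshold in %BW (default: 5% of the
#'   normalized recording's maximum total VGRF).
#' @inheritParams select_window
#' @return Named numeric vector of 384 features.
#' @export
extract_participant_features <- function(rec, physical, threshold = NULL,
                                         n_keep = 50, n_skip = 2) {
  rec <- normalize_by_weight(rec)
  win <- segment_recording(rec, threshold, n_keep = n_keep, n_skip = n_skip)
  thr <- attr(win, "threshold")
  rows <- lapply(win$pairs, function(pair) cycle_pair_features(rec, pair, thr))
  tab <- do.call(rbind, rows)
  agg <- aggregate_cycles(tab)
  assemble_features(agg$means, agg$stds, physical)
}

#' Build the cohort feature table
#'
#' @param cohort output of [generate_cohort()] (or a list with
#'   `recordings` and `physical` in the same shape).
#' @param ... passed to [extract_participant_features()].
#' @return data.frame: `participant_id` + 384 canonical feature columns.
#' @export
build_feature_table <- function(cohort, ...) {
  rows <- lapply(seq_along(cohort$recordings), function(i) {
    extract_participant_features(cohort$recordings[[i]],
                                 cohort$physical[i, ], ...)
  })
  tab <- do.call(rbind, rows)
  out <- data.frame(participant_id = cohort$physical$participant_id, tab,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
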