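# Synthetic plantar-pressure generator: bimodal-stance vertical ground
# reaction force (VGRF) waveforms over 8 sensors per foot with known
# ground-truth landmarks, so every downstream stage can be validated
# without patient data.

#' Insole sensor layout
#'
#' Eight sensors per foot in a normalized foot coordinate system
#' (x: medial-lateral in units of foot width, y: anterior-posterior in
#' units of foot length, both in \[0, 1\]). Sensors 1-4 cover the
#' forefoot, 5-6 the midfoot, 7-8 the heel.
#'
#' @param coords 8x2 numeric matrix of normalized (x, y) coordinates; the
#'   default mimics a typical insole: big-toe/metatarsal sensors anterior,
#'   heel sensors posterior.
#' @param foot_length,foot_width physical dimensions in mm (metadata used
#'   when converting raw shoe coordinates; features use normalized units).
#' @return An object of class `sensor_layout`.
#' @export
sensor_layout <- function(coords = NULL, foot_length = 250, foot_width = 95) {
  if (is.null(coords)) {
    coords <- rbind(
      c(0.30, 0.90),  # 1: hallux / medial forefoot, most anterior
      c(0.35, 0.75),  # 2: medial metatarsal
      c(0.55, 0.78),  # 3: central metatarsal
      c(0.75, 0.72),  # 4: lateral metatarsal
      c(0.40, 0.45),  # 5: medial midfoot
      c(0.65, 0.45),  # 6: lateral midfoot
      c(0.40, 0.12),  # 7: medial heel
      c(0.60, 0.10)   # 8: lateral heel
    )
  }
  coords <- as.matrix(coords)
  assert_that(nrow(coords) == 8 && ncol(coords) == 2,
              "layout requires exactly 8 sensors with (x, y) coordinates")
  assert_that(all(coords >= 0 & coords <= 1),
              "normalized sensor coordinates must lie in [0,1]x[0,1]")
  assert_that(foot_length > 0 && foot_width > 0, "foot dimensions must be positive")
  structure(list(
    coords = coords,
    foot_length = foot_length,
    foot_width = foot_width,
    region_map = list(forefoot = 1:4, midfoot = 5:6, heel = 7:8)
  ), class = "sensor_layout")
}

#' Gait waveform parameters
#'
#' Parameterizes the per-cycle bimodal stance waveform: total VGRF rises
#' from heel strike to a first (heel-loading) peak, dips to a mid-stance
#' valley, rises to a second (push-off) peak, and returns to zero at
#' toe-off; swing carries no load. Time fractions are fractions of the
#' full gait cycle.
#'
#' @param cycle_duration gait cycle time T in seconds.
#' @param stance_fraction stance duration as a fraction of T (0 < f < 1);
#'   values above 0.5 produce double-support overlap between feet.
#' @param peak1_time_fraction,peak2_time_fraction cycle-time fractions of
#'   the two VGRF peaks; must satisfy p1 < p2 < stance_fraction.
#' @param peak1_amp,peak2_amp,valley_amp total-VGRF amplitudes at the two
#'   peaks and the valley, in fractions of body weight (%BW);
#'   valley_amp < min(peak1_amp, peak2_amp).
#' @param region_shares relative loading weights for forefoot, midfoot,
#'   heel applied to the time-varying regional activation profile
#'   (renormalized to sum to 1 at every stance sample).
#' @param sensor_shares list with per-region within-region sensor weights
#'   (forefoot 4, midfoot 2, heel 2; each summing to 1).
#' @param cycle_jitter_sd fractional SD of cycle-to-cycle variability in
#'   duration and amplitude (0 = perfectly repeatable gait).
#' @param asym_amp,asym_time fractional left-right asymmetry: the right
#'   foot's amplitudes are scaled by (1 + asym_amp) and its stance
#'   fraction by (1 + asym_time).
#' @param n_cycles number of gait cycles to generate per foot.
#' @param seed integer seed for the jitter draws.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(cycle_duration = 1.1,
                            stance_fraction = 0.62,
                            peak1_time_fraction = 0.17,
                            peak2_time_fraction = 0.47,
                            peak1_amp = 1.15,
                            peak2_amp = 1.10,
                            valley_amp = 0.75,
                            region_shares = c(forefoot = 1, midfoot = 0.4, heel = 1),
                            sensor_shares = NULL,
                            cycle_jitter_sd = 0,
                            asym_amp = 0,
                            asym_time = 0,
                            n_cycles = 55,
                            seed = 1L) {
  if (is.null(sensor_shares)) {
    sensor_shares <- list(
      forefoot = c(0.28, 0.30, 0.22, 0.20),
      midfoot = c(0.5, 0.5),
      heel = c(0.55, 0.45)
    )
  }
  p <- structure(as.list(environment()), class = "waveform_params")
  validate_waveform_params(p)
  p
}

validate_waveform_params <- function(p) {
  assert_that(p$stance_fraction > 0 && p$stance_fraction < 1,
              "stance_fraction must be in (0, 1)")
  assert_that(p$peak1_time_fraction < p$peak2_time_fraction &&
              p$peak2_time_fraction < p$stance_fraction,
              "peak ordering violated: need peak1 < peak2 < stance_fraction")
  assert_that(p$peak1_time_fraction > 0, "peak1_time_fraction must be positive")
  assert_that(p$valley_amp < min(p$peak1_amp, p$peak2_amp),
              "valley_amp must be below both peak amplitudes")
  assert_that(all(c(p$peak1_amp, p$peak2_amp, p$valley_amp) >= 0),
              "amplitudes must be nonnegative")
  assert_that(p$cycle_jitter_sd >= 0, "cycle_jitter_sd must be >= 0")
  assert_that(p$n_cycles >= 1, "need at least one cycle")
  assert_that(p$cycle_duration > 0, "cycle_duration must be positive")
  for (r in names(p$sensor_shares)) {
    s <- p$sensor_shares[[r]]
    assert_that(all(s >= 0) && abs(sum(s) - 1) < 1e-8,
                "sensor shares for %s must be nonnegative and sum to 1", r)
  }
  invisible(p)
}

# Evaluate one stance waveform at absolute sample times for a cycle
# starting at `start` with duration Ti: piecewise cubic Hermite segments
# with zero slope at every landmark knot (smoothstep between control
# points). Each segment is monotone, so the sampled curve attains the
# planted peak/valley amplitudes exactly at the knots with no overshoot,
# and is exactly zero through swing.
stance_spline <- function(start, Ti, p1, p2, stance_f, a1, a2, av) {
  pv <- (p1 + p2) / 2
  kt <- start + c(0, p1, pv, p2, stance_f, 1) * Ti
  kv <- c(0, a1, av, a2, 0, 0)
  function(t) {
    seg <- findInterval(t, kt, rightmost.closed = TRUE)
    seg[seg < 1] <- 1L
    seg[seg >= length(kt)] <- length(kt) - 1L
    s <- (t - kt[seg]) / (kt[seg + 1] - kt[seg])
    s <- pmin(pmax(s, 0), 1)
    kv[seg] + (kv[seg + 1] - kv[seg]) * (3 * s^2 - 2 * s^3)
  }
}

# Regional activation profile at stance progress v in [0,1]: heel loads
# early, forefoot late, midfoot in between; the unweighted profile
# (1-v)^2 + 2v(1-v) + v^2 sums to 1 identically, so after applying the
# region_shares weights a single renormalization preserves the total.
region_profile <- function(v, region_shares) {
  raw <- cbind(
    forefoot = region_shares[["forefoot"]] * v^2,
    midfoot = region_shares[["midfoot"]] * 2 * v * (1 - v),
    heel = region_shares[["heel"]] * (1 - v)^2
  )
  raw / rowSums(raw)
}

generate_foot <- function(params, t_offset, amp_scale, stance_scale, n_samples, seed) {
  p <- params
  stance_f <- min(p$stance_fraction * stance_scale, 0.95)
  jit <- with_seed(seed, list(
    dur = stats::rnorm(p$n_cycles, 0, p$cycle_jitter_sd),
    amp = stats::rnorm(p$n_cycles, 0, p$cycle_jitter_sd)
  ))
  durations <- p$cycle_duration * pmax(1 + jit$dur, 0.5)
  starts <- t_offset + c(0, cumsum(durations[-p$n_cycles]))
  tgrid <- (seq_len(n_samples) - 1) * DT

  channels <- matrix(0, n_samples, 8)
  sensor_w <- numeric(8)
  truth <- vector("list", p$n_cycles)
  region_cols <- list(forefoot = 1:4, midfoot = 5:6, heel = 7:8)

  for (i in seq_len(p$n_cycles)) {
    s <- starts[i]; Ti <- durations[i]
    a <- amp_scale * pmax(1 + jit$amp[i], 0.05)
    f <- stance_spline(s, Ti, p$peak1_time_fraction, p$peak2_time_fraction,
                       stance_f, a * p$peak1_amp, a * p$peak2_amp, a * p$valley_amp)
    idx <- which(tgrid >= s & tgrid < s + Ti)
    if (!length(idx)) next
    tot <- pmax(f(tgrid[idx]), 0)
    in_stance <- tgrid[idx] < s + stance_f * Ti
    if (any(in_stance)) {
      v <- (tgrid[idx][in_stance] - s) / (stance_f * Ti)
      w <- region_profile(v, p$region_shares)
      for (r in names(region_cols)) {
        cols <- region_cols[[r]]
        channels[idx[in_stance], cols] <- channels[idx[in_stance], cols] +
          (tot[in_stance] * w[, r]) %o% p$sensor_shares[[r]]
      }
    }
    pos <- idx[tot > 0]
    truth[[i]] <- c(
      start = if (length(idx)) idx[1] else NA_integer_,
      heel_strike = if (length(pos)) pos[1] else NA_integer_,
      peak1 = round((s + p$peak1_time_fraction * Ti) / DT) + 1L,
      valley = round((s + (p$peak1_time_fraction + p$peak2_time_fraction) / 2 * Ti) / DT) + 1L,
      peak2 = round((s + p$peak2_time_fraction * Ti) / DT) + 1L,
      toe_off = which(tgrid >= s + stance_f * Ti)[1]
    )
  }
  list(channels = channels,
       truth = do.call(rbind, truth),
       span = starts[p$n_cycles] + durations[p$n_cycles])
}

#' Generate one bilateral pressure recording
#'
#' Builds synchronized left/right Tx8 channel matrices at 20 Hz whose
#' per-foot total pressure is bimodal within each stance and exactly zero
#' during swing, with the right foot phase-shifted by half a cycle.
#' Ground-truth landmark indices for every cycle are attached for
#' validation of the segmentation stage.
#'
#' @param params a [waveform_params()] object.
#' @param layout a [sensor_layout()] object.
#' @param body_weight body weight in kg; channels are emitted in raw
#'   units (body_weight x %BW), as the shoe hardware would report.
#' @param participant_id identifier carried through the pipeline.
#' @return An object of class `pressure_recording` with elements `left`,
#'   `right` (Tx8 matrices), `sampling_rate`, `body_weight`, `layout`,
#'   `units` ("raw"), and `ground_truth` (per-foot landmark index tables).
#' @export
generate_recording <- function(params, layout = sensor_layout(),
                               body_weight = 60, participant_id = "P01") {
  validate_waveform_params(params)
  assert_that(body_weight > 0, "body_weight must be positive")
  p <- params
  total_time <- (p$n_cycles + 1.5) * p$cycle_duration * (1 + 4 * p$cycle_jitter_sd)
  n_samples <- ceiling(total_time / DT)

  left <- generate_foot(p, t_offset = 0, amp_scale = 1, stance_scale = 1,
                        n_samples = n_samples, seed = p$seed)
  # Same jitter draws for both feet: with zero asymmetry the right matrix
  # is exactly the left one shifted by the half-cycle phase offset.
  right <- generate_foot(p, t_offset = 0.5 * p$cycle_duration,
                         amp_scale = 1 + p$asym_amp,
                         stance_scale = 1 + p$asym_time,
                         n_samples = n_samples, seed = p$seed)
  n_keep <- ceiling(max(left$span, right$span) / DT) + 2L
  n_keep <- min(n_keep, n_samples)

  structure(list(
    participant_id = participant_id,
    left = body_weight * left$channels[seq_len(n_keep), , drop = FALSE],
    right = body_weight * right$channels[seq_len(n_keep), , drop = FALSE],
    sampling_rate = SAMPLING_RATE,
    body_weight = body_weight,
    layout = layout,
    units = "raw",
    ground_truth = list(left = left$truth, right = right$truth)
  ), class = "pressure_recording")
}

#' Cohort specification for the synthetic study
#'
#' Defines per-participant distributions of physical characteristics and
#' waveform parameters, plus the label-generation model: each functional
#' test time is linear in gait parameters and physical covariates with
#' Gaussian noise, y = b0 + sum_k b_k * param_k + noise. The coefficient
#' names declare which parameters carry signal, enabling recovery tests.
#'
#' Default distributions emulate an elderly knee-osteoarthritis cohort:
#' age 62.95 (SD 8.4) years, height 158.08 (SD 7.85) cm, weight 61.33
#' (SD 10.47) kg, and label scales of roughly 28.6 (SD 6.2) s for the
#' 40-m fast-paced walk test and 11.4 (SD 3.0) s for the timed
#' up-and-go test.
#'
#' @param n_participants cohort size (>= 2).
#' @param seed master seed; all draws derive from it.
#' @param age,height,weight `c(mean, sd)` pairs for physical
#'   characteristics (age truncated to \[45, 85\]); BMI is computed.
#' @param cycle_duration,stance_fraction `c(mean, sd)` pairs for the
#'   per-participant waveform sampler.
#' @param asym_sd SD of the half-normal per-participant amplitude
#'   asymmetry magnitude.
#' @param jitter_range range of the uniform per-participant
#'   cycle-to-cycle variability SD.
#' @param n_cycles gait cycles generated per participant.
#' @param label_coefs named list with elements `fpwt40` and `tugt`, each a
#'   named coefficient vector over `intercept`, gait parameters
#'   (`cycle_duration`, `stance_fraction`, `asym_amp`, `cycle_jitter_sd`)
#'   and physical covariates (`age`, `height`, `weight`, `bmi`).
#' @param label_noise_sd named vector of Gaussian label noise SDs (s).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 92,
                        seed = 1L,
                        age = c(62.95, 8.4),
                        height = c(158.08, 7.85),
                        weight = c(61.33, 10.47),
                        cycle_duration = c(1.1, 0.08),
                        stance_fraction = c(0.62, 0.02),
                        asym_sd = 0.04,
                        jitter_range = c(0.01, 0.05),
                        n_cycles = 55,
                        label_coefs = NULL,
                        label_noise_sd = c(fpwt40 = 1.5, tugt = 0.8)) {
  if (is.null(label_coefs)) {
    label_coefs <- list(
      fpwt40 = c(intercept = -25, cycle_duration = 8, stance_fraction = 10,
                 asym_amp = 20, age = 0.6),
      tugt = c(intercept = -10.5, cycle_duration = 3, stance_fraction = 4,
               asym_amp = 10, age = 0.25)
    )
  }
  assert_that(n_participants >= 2, "n_participants must be >= 2")
  assert_that(all(label_noise_sd >= 0), "label noise sd must be >= 0")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples per-participant physical characteristics and waveform
#' parameters, generates one pressure recording each, and produces label
#' pairs from the spec's linear label model.
#'
#' @param spec a [cohort_spec()] object.
#' @return A list with `recordings` (list of `pressure_recording`),
#'   `physical` (data.frame: participant_id, age, height, weight, bmi),
#'   `labels` (data.frame: participant_id, fpwt40_s, tugt_s), `truth`
#'   (per-participant gait parameter table), and `signal_params` (names
#'   of gait parameters with nonzero label coefficients, for recovery
#'   tests).
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_participants
  draws <- with_seed(spec$seed, {
    list(
      age = pmin(pmax(stats::rnorm(n, spec$age[1], spec$age[2]), 45), 85),
      height = stats::rnorm(n, spec$height[1], spec$height[2]),
      weight = pmax(stats::rnorm(n, spec$weight[1], spec$weight[2]), 35),
      T = pmax(stats::rnorm(n, spec$cycle_duration[1], spec$cycle_duration[2]), 0.7),
      stance = pmin(pmax(stats::rnorm(n, spec$stance_fraction[1], spec$stance_fraction[2]), 0.55), 0.72),
      asym = abs(stats::rnorm(n, 0, spec$asym_sd)),
      jitter = stats::runif(n, spec$jitter_range[1], spec$jitter_range[2]),
      eps40 = stats::rnorm(n, 0, spec$label_noise_sd[["fpwt40"]]),
      epstug = stats::rnorm(n, 0, spec$label_noise_sd[["tugt"]]),
      seeds = sample.int(1e6, n)
    )
  })
  bmi <- draws$weight / (draws$height / 100)^2
  ids <- sprintf("P%03d", seq_len(n))
  layout <- sensor_layout()

  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    wp <- waveform_params(
      cycle_duration = draws$T[i],
      stance_fraction = draws$stance[i],
      cycle_jitter_sd = draws$jitter[i],
      asym_amp = draws$asym[i],
      n_cycles = spec$n_cycles,
      seed = draws$seeds[i]
    )
    recordings[[i]] <- generate_recording(wp, layout, body_weight = draws$weight[i],
                                          participant_id = ids[i])
  }

  covars <- data.frame(
    intercept = 1, cycle_duration = draws$T, stance_fraction = draws$stance,
    asym_amp = draws$asym, cycle_jitter_sd = draws$jitter,
    age = draws$age, height = draws$height, weight = draws$weight, bmi = bmi
  )
  label_for <- function(coefs, noise) {
    b <- numeric(ncol(covars)); names(b) <- names(covars)
    b[names(coefs)] <- coefs
    as.numeric(as.matrix(covars) %*% b) + noise
  }
  y40 <- label_for(spec$label_coefs$fpwt40, draws$eps40)
  ytug <- label_for(spec$label_coefs$tugt, draws$epstug)
  if (stats::sd(y40) == 0 && stats::sd(ytug) == 0) {
    warning("degenerate cohort spec: zero-variance labels", call. = FALSE)
  }
  assert_that(all(y40 > 0) && all(ytug > 0),
              "label model produced nonpositive test times; adjust coefficients")

  gait_names <- c("cycle_duration", "stance_fraction", "asym_amp", "cycle_jitter_sd")
  signal <- unique(unlist(lapply(spec$label_coefs, function(cf) {
    intersect(names(cf)[cf != 0], gait_names)
  })))

  list(
    recordings = recordings,
    physical = data.frame(participant_id = ids, age = draws$age,
                          height = draws$height, weight = draws$weight, bmi = bmi),
    labels = data.frame(participant_id = ids, fpwt40_s = y40, tugt_s = ytug),
    truth = cbind(data.frame(participant_id = ids), covars[-1]),
    signal_params = signal
  )
}

#' Write / read a recording in the package CSV dialect
#'
#' Columns `t, L1..L8, R1..R8` (raw pressure units) with a JSON sidecar
#' (`<path>.json`) carrying body weight, foot dimensions, sensor
#' coordinates, and units.
#'
#' @param rec a `pressure_recording`.
#' @param path CSV file path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `pressure_recording`.
#' @export
write_recording <- function(rec, path) {
  n <- nrow(rec$left)
  df <- data.frame(t = (seq_len(n) - 1) * DT, rec$left, rec$right)
  names(df) <- c("t", paste0("L", 1:8), paste0("R", 1:8))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    participant_id = rec$participant_id,
    body_weight = rec$body_weight,
    sampling_rate = rec$sampling_rate,
    units = rec$units,
    foot_length = rec$layout$foot_length,
    foot_width = rec$layout$foot_width,
    sensor_coords = rec$layout$coords
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param path CSV file path written by `write_recording()`.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(
    participant_id = meta$participant_id,
    left = as.matrix(df[paste0("L", 1:8)]),
    right = as.matrix(df[paste0("R", 1:8)]),
    sampling_rate = meta$sampling_rate,
    body_weight = meta$body_weight,
    layout = sensor_layout(coords = meta$sensor_coords,
                           foot_length = meta$foot_length,
                           foot_width = meta$foot_width),
    units = meta$units,
    ground_truth = NULL
  ), class = "pressure_recording")
}
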