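test_that("peak plantar pressure features match definitions and flag undefined ratios", {
  cyc <- random_cycle(1)
  cyc$mat[] <- 0
  z <- ppp_features(cyc)
  expect_true(all(z[1:13] == 0))
  expect_true(all(is.na(z[c("4/2_PPP", "8/7_PPP")])))

  cyc2 <- random_cycle(2)
  cyc2$mat[, 2] <- cyc2$mat[, 4]  # equal medial/lateral forefoot peaks
  expect_equal(ppp_features(cyc2)[["4/2_PPP"]], 1)
})

test_that("pressure gradients on a constant-slope ramp equal the slope", {
  n <- 12
  cyc <- structure(list(
    mat = matrix(rep(2 * (0:(n - 1)) * 0.05 / 8, 8), n, 8),
    landmarks = list(heel_strike = 1L, peak1 = 4L, valley = 6L, peak2 = 8L,
                     toe_off = 11L, cycle_end = 12L),
    dt = 0.05), class = "gait_cycle")
  pg <- pg_features(cyc)
  expect_equal(pg[["1_MaxPG"]], 2 / 8)
  expect_equal(pg[["1_MinPG"]], 2 / 8)
  expect_equal(pg[["1-4_MaxPG"]], 2 / 2)  # four channels summed
})

test_that("valley gradient sum reproduces the piecewise-linear arithmetic", {
  # total VGRF 1.0 -> 0.6 in 4 steps then 0.6 -> 1.0 in 4 steps, dt = 0.05
  total <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.7, 0.8, 0.9, 1.0, 0.5, 0.1, 0)
  mat <- matrix(0, length(total), 8); mat[, 1] <- total
  cyc <- structure(list(
    mat = mat,
    landmarks = list(heel_strike = 1L, peak1 = 1L, valley = 5L, peak2 = 9L,
                     toe_off = 12L, cycle_end = 12L),
    dt = 0.05), class = "gait_cycle")
  expect_equal(pg_features(cyc)[["valleyPG"]], 8 * (0.1 / 0.05))
})

test_that("max/min pressure gradients equal brute force over consecutive differences", {
  for (s in 1:5) {
    cyc <- random_cycle(s)
    pg <- pg_features(cyc)
    for (j in c(1, 5, 8)) {
      d <- (cyc$mat[-1, j] - cyc$mat[-nrow(cyc$mat), j]) / cyc$dt
      expect_equal(pg[[paste0(j, "_MaxPG")]], max(d))
      expect_equal(pg[[paste0(j, "_MinPG")]], min(d))
    }
  }
})

test_that("temporal features reproduce the stance/swing arithmetic", {
  # stance 0.6 s, swing 0.4 s, first peak 0.2 s after heel strike
  cyc <- structure(list(
    mat = matrix(1, 21, 8),
    landmarks = list(heel_strike = 1L, peak1 = 5L, valley = 8L, peak2 = 11L,
                     toe_off = 13L, cycle_end = 21L),
    dt = 0.05), class = "gait_cycle")
  tf <- temporal_features(cyc)
  expect_equal(tf[["t_st/sw"]], 1.5)
  expect_equal(tf[["t_T"]], 1.0)
  expect_equal(tf[["t_st/T"]], 0.6)
  expect_equal(tf[["t_t1/T"]], 0.2)
})

test_that("pressure-time integrals match closed forms and a refined-grid oracle", {
  rect <- structure(list(
    mat = matrix(0.8 / 8, 11, 8),
    landmarks = list(heel_strike = 1L, peak1 = 3L, valley = 5L, peak2 = 8L,
                     toe_off = 11L, cycle_end = 11L),
    dt = 0.05), class = "gait_cycle")
  expect_equal(pti_features(rect)[["PTI_st"]], 0.4)

  tri_total <- seq(0, 1, length.out = 5)  # 0 -> 1 over 0.2 s, apex = peak1
  tri <- structure(list(
    mat = matrix(rep(tri_total / 8, 8), 5, 8),
    landmarks = list(heel_strike = 1L, peak1 = 5L, valley = 5L, peak2 = 5L,
                     toe_off = 5L, cycle_end = 5L),
    dt = 0.05), class = "gait_cycle")
  expect_equal(pti_features(tri)[["PTI_1"]], 0.1)

  # smooth closed-form waveform: trapezoid at 20 Hz vs a 100x-refined grid
  f <- function(t) sin(pi * t / 0.6)^2
  tt <- seq(0, 0.6, by = 0.05)
  mat <- matrix(rep(f(tt) / 8, 8), length(tt), 8)
  cyc <- structure(list(
    mat = mat,
    landmarks = list(heel_strike = 1L, peak1 = 4L, valley = 7L, peak2 = 10L,
                     toe_off = 13L, cycle_end = 13L),
    dt = 0.05), class = "gait_cycle")
  fine <- seq(0, 0.6, by = 0.0005)
  oracle <- sum((f(fine)[-1] + f(fine)[-length(fine)]) / 2 * 0.0005)
  expect_equal(pti_features(cyc)[["PTI_st"]], oracle, tolerance = 5e-3)
})

test_that("COP features follow the pressure-weighted mean definition", {
  layout <- sensor_layout()
  one <- random_cycle(4)
  one$mat[] <- 0; one$mat[2:15, 3] <- 0.5  # single active sensor
  cf <- cop_features(one, layout, threshold = 0.05)
  expect_equal(cf[["xcop_mean"]], layout$coords[3, 1])
  expect_equal(cf[["ycop_mean"]], layout$coords[3, 2])
  expect_equal(cf[["cop_len"]], 0)
  expect_equal(cf[["cop_MRD"]], 0)
  expect_equal(cf[["cop_SRD"]], 0)

  two <- random_cycle(5)
  two$mat[] <- 0; two$mat[2:15, c(1, 8)] <- 0.3  # equal pressure on two sensors
  cf2 <- cop_features(two, layout, threshold = 0.05)
  expect_equal(cf2[["xcop_mean"]], mean(layout$coords[c(1, 8), 1]))
  expect_equal(cf2[["ycop_mean"]], mean(layout$coords[c(1, 8), 2]))

  # brute-force oracle on a random stance
  cyc <- random_cycle(6)
  cf3 <- cop_features(cyc, layout, threshold = 0.05)
  stance <- 1:18
  keep <- stance[rowSums(cyc$mat[stance, ]) > 0.05]
  px <- py <- numeric(length(keep))
  for (i in seq_along(keep)) {
    w <- cyc$mat[keep[i], ]
    px[i] <- sum(w * layout$coords[, 1]) / sum(w)
    py[i] <- sum(w * layout$coords[, 2]) / sum(w)
  }
  expect_equal(cf3[["xcop_mean"]], mean(px))
  expect_equal(cf3[["cop_len"]],
               sum(sqrt(diff(px)^2 + diff(py)^2)))
  rd <- sqrt((px - mean(px))^2 + (py - mean(py))^2)
  expect_equal(cf3[["cop_MRD"]], mean(rd))
  expect_equal(cf3[["cop_SRD"]], sd(rd))
})

test_that("bipedal support times recover the planted double-support overlap", {
  # stance fraction 0.65, T = 1.0 s, half-cycle offset -> 0.15 s overlap
  # per step, two steps per cycle
  p <- waveform_params(cycle_duration = 1.0, stance_fraction = 0.65,
                       peak1_time_fraction = 0.15, peak2_time_fraction = 0.5,
                       n_cycles = 10, seed = 1)
  rec <- normalize_by_weight(generate_recording(p, body_weight = 60))
  tl <- total_vgrf(rec, "left"); tr <- total_vgrf(rec, "right")
  gt <- rec$ground_truth$left
  bi <- bipedal_support_times(tl, tr, gt[4, "start"], gt[5, "start"],
                              threshold = 0.05 * max(tl))
  expect_equal(bi[["t_double_support"]], 0.3, tolerance = 0.34)  # 2 x 0.15 s +- 2 samples
  expect_gt(bi[["t_single_support"]], 0.5)
})

test_that("cycle aggregation matches brute-force means and SDs", {
  set.seed(8)
  tab <- matrix(rnorm(20 * 110), 20, 110)
  colnames(tab) <- c(plantargait:::foot_feature_names("L"),
                     plantargait:::foot_feature_names("R"),
                     plantargait:::bipedal_feature_names())
  tab[3, 5] <- NA
  agg <- aggregate_cycles(tab)
  expect_length(agg$means, 110)
  expect_length(agg$stds, 108)
  expect_equal(agg$means[[5]], mean(tab[, 5], na.rm = TRUE))
  expect_equal(agg$stds[[paste0(colnames(tab)[5], "_STD")]],
               sd(tab[, 5], na.rm = TRUE))
  # alternating values
  tab2 <- tab; tab2[, 1] <- rep(c(2, 6), 10)
  expect_equal(aggregate_cycles(tab2)$means[[1]], 4)
})

test_that("symmetry index is symmetric, zero at equality, and 100 at 3:1", {
  expect_equal(symmetry_index(5, 5), 0)
  expect_equal(symmetry_index(3, 1), 100)
  expect_true(is.na(symmetry_index(0, 0)))
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(symmetry_index(a, b), symmetry_index(b, a))
  expect_true(all(symmetry_index(abs(a), abs(b)) >= 0))
})

test_that("weak foot selection follows anterior-posterior COP variability with left tie-break", {
  f <- fixture_features(jitter = 0.02, asym = 0.03, seed = 3)
  means_names <- c(plantargait:::foot_feature_names("L"),
                   plantargait:::foot_feature_names("R"),
                   plantargait:::bipedal_feature_names())
  means <- setNames(rnorm(110, 10), means_names)
  stds <- setNames(abs(rnorm(108)), paste0(means_names[1:108], "_STD"))
  means[["L_ycop_std"]] <- 2; means[["R_ycop_std"]] <- 1
  wk <- weak_foot_features(means, stds)
  expect_identical(wk$weak_foot, "left")
  expect_equal(wk$features[["W_peak1"]], means[["L_peak1"]])
  expect_equal(wk$features[["W_peak1_STD"]], stds[["L_peak1_STD"]])
  means[["R_ycop_std"]] <- 2  # exact tie -> left
  expect_identical(weak_foot_features(means, stds)$weak_foot, "left")
  means[["R_ycop_std"]] <- 3
  expect_identical(weak_foot_features(means, stds)$weak_foot, "right")
})

test_that("participant vectors have the exact feature inventory", {
  f <- fixture_features(jitter = 0.02, asym = 0.03, seed = 3)
  expect_length(f, 384)
  expect_identical(names(f), participant_feature_names())
  expect_false(any(is.na(f)))
  dict <- feature_dictionary()
  counts <- table(dict$group)
  expect_equal(unname(counts[c("PPP", "PG", "temporal", "PTI", "COP",
                               "SI", "STD", "weak", "physical")]),
               c(30, 50, 12, 4, 14, 54, 108, 108, 4), ignore_attr = TRUE)
})

test_that("zero-asymmetry zero-jitter participants have SI = 0 and STD = 0", {
  f <- fixture_features(jitter = 0, asym = 0)
  si <- f[startsWith(names(f), "SI_")]
  stds <- f[endsWith(names(f), "_STD") & !startsWith(names(f), "W_")]
  expect_length(si, 54)
  expect_length(stds, 108)
  expect_equal(max(abs(si)), 0, tolerance = 1e-8)
  expect_equal(max(abs(stds)), 0, tolerance = 1e-8)
})

test_that("mirror property: swapping feet swaps L/R features and keeps SI", {
  p <- waveform_params(cycle_jitter_sd = 0, asym_amp = 0.08, asym_time = 0.03,
                       seed = 2)
  rec <- generate_recording(p, body_weight = 65)
  swapped <- rec
  swapped$left <- rec$right; swapped$right <- rec$left
  swapped$ground_truth <- list(left = rec$ground_truth$right,
                               right = rec$ground_truth$left)
  f1 <- extract_participant_features(rec, fixture_physical())
  f2 <- extract_participant_features(swapped, fixture_physical())
  base <- plantargait:::base_feature_names()
  Ln <- plantargait:::foot_feature_names("L", base)
  Rn <- plantargait:::foot_feature_names("R", base)
  expect_equal(unname(f2[Ln]), unname(f1[Rn]), tolerance = 1e-10)
  expect_equal(unname(f2[Rn]), unname(f1[Ln]), tolerance = 1e-10)
  expect_equal(f2[startsWith(names(f2), "SI_")], f1[startsWith(names(f1), "SI_")],
               tolerance = 1e-10)
  expect_equal(f2[startsWith(names(f2), "W_")], f1[startsWith(names(f1), "W_")],
               tolerance = 1e-10)
})

test_that("scale property: pressure scaling propagates to load features only", {
  rec <- fixture_recording(jitter = 0.02, asym = 0.03, seed = 3)
  f1 <- fixture_features(jitter = 0.02, asym = 0.03, seed = 3)
  scaled <- rec
  scaled$left <- rec$left * 3; scaled$right <- rec$right * 3
  f3 <- extract_participant_features(scaled, fixture_physical())
  dict <- feature_dictionary()
  load_groups <- dict$name[dict$group %in% c("PPP", "PG", "PTI") &
                             !grepl("/", dict$name) & !grepl("_STD$", dict$name) &
                             !startsWith(dict$name, "SI_") & !startsWith(dict$name, "W_")]
  expect_equal(unname(f3[load_groups]), unname(3 * f1[load_groups]), tolerance = 1e-9)
  temporal <- c("L_t_st/T", "R_t_st/T", "L_t_T", "R_t_T")
  cop <- c("L_xcop_mean", "R_ycop_mean", "L_cop_len")
  si <- names(f1)[startsWith(names(f1), "SI_")]
  expect_equal(f3[c(temporal, cop, si)], f1[c(temporal, cop, si)], tolerance = 1e-9)
})
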