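# Feature extraction: delineation, global and local features, schema.

test_that("vectorized sample entropy replicates the pracma reference exactly", {
  set.seed(99)
  for (i in 1:15) {
    x <- rnorm(sample(40:200, 1))
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy_fast(x, 2L, r),
                 pracma::sample_entropy(x, edim = 2, r = r),
                 tolerance = 1e-12)
  }
})

test_that("sample entropy of a sinusoid is below that of white noise at equal SD", {
  set.seed(4)
  s <- sin(seq(0, 8 * pi, length.out = 200))
  n <- rnorm(200, 0, sd(s))
  expect_lt(sample_entropy_fast(s), sample_entropy_fast(n))
})

test_that("delineation recovers a clean Gaussian P support within 4 ms", {
  avg <- make_gauss_avg(support_ms = 120)
  del <- delineate_pwave(avg)
  expect_lt(abs(del$duration_ms - 120), 4)
  expect_true(del$onset_idx >= 1 && del$offset_idx <= 300)
})

test_that("flat or sub-noise-floor windows are invalid observations", {
  flat <- make_avg(matrix(0, 300, 12))
  expect_null(delineate_pwave(flat))
  tiny <- make_gauss_avg(amp = 0.005)  # below the 10 uV floor
  expect_null(delineate_pwave(tiny))
  expect_null(extract_features(flat, 50, 1))
})

test_that("FWHM matches closed forms for Gaussian and triangular pulses", {
  fs <- 1000
  for (sgm in c(10, 20, 30)) {
    g <- exp(-((seq_len(600) - 300)^2) / (2 * sgm^2))
    expect_lt(abs(fwhm(g, fs) - 2.355 * sgm), 1.5)
  }
  tri <- c(seq(0, 1, length.out = 61), seq(1, 0, length.out = 61)[-1])
  expect_lt(abs(fwhm(tri, fs) - 60) , 2)  # base 120 ms -> FWHM 60 ms
  # strict > rule: samples exactly at half maximum are excluded
  x <- c(0, 0.5, 1, 0.5, 0)
  expect_equal(fwhm(x, 1000), 1)
})

test_that("terminal force in V1 follows depth x duration and its zero/scaling laws", {
  fs <- 1000
  t <- seq_len(300)
  pos <- 0.1 * sin(pi * pmax(0, pmin(1, (t - 80) / 160)))  # positive lobe 80-240
  neg <- ifelse(t >= 221 & t <= 260, -0.05, 0)  # terminal plateau overlaps the tail
  waves <- matrix(rep(pos, 12), ncol = 12)
  waves[, 7] <- pos * 0.8 + neg
  avg <- make_avg(waves)
  del <- delineate_pwave(avg)
  v <- ptfv1(avg, del)
  # oracle: 50 uV deep, ~40 ms long -> 2.0 uV.s
  expect_equal(v, 2.0, tolerance = 0.25)
  # doubling the terminal depth doubles the value
  waves2 <- waves
  waves2[, 7] <- pos * 0.8 + 2 * neg
  avg2 <- make_avg(waves2)
  v2 <- ptfv1(avg2, delineate_pwave(avg2))
  expect_equal(v2 / v, 2, tolerance = 0.1)
  # monophasic positive P in V1 gives zero
  mono <- make_gauss_avg()
  expect_equal(ptfv1(mono, delineate_pwave(mono)), 0)
})

test_that("P-wave axis follows atan2 of the net limb-lead areas", {
  w <- gauss_window()
  m0 <- matrix(0, 300, 12)
  m0[, 1] <- w                       # lead I only
  m0[, 2] <- w                       # keep the composite peak healthy
  avg <- make_avg(m0)
  expect_equal(pwave_axis(avg, delineate_pwave(avg)), 0, tolerance = 1e-6)
  m45 <- m0
  m45[, 6] <- w                      # equal net areas in I and aVF
  avg45 <- make_avg(m45)
  expect_equal(pwave_axis(avg45, delineate_pwave(avg45)), 45, tolerance = 1e-6)
})

test_that("axis parameterized beats are recovered within 5 degrees end to end", {
  for (ax in c(0, 30, 60, 90)) {
    m <- beat_morphology(p_axis_deg = ax, p_mag_mv = 0.18,
                         v1_terminal_depth_mv = 0)
    rb <- render_beat(m, fs = 1000)
    idx <- which(rb$t_ms >= -350 & rb$t_ms < -50)
    avg <- make_avg(rb$signal[idx, ])
    est <- pwave_axis(avg, delineate_pwave(avg))
    expect_lt(abs(est - ax), 5)
  }
})

test_that("local features match closed-form oracles", {
  fs <- 1000
  # triangle, peak 100 uV, base 120 ms -> area 1/2 * 0.12 s * 100 uV = 6 uV.s
  tri <- c(rep(0, 90), seq(0, 0.1, length.out = 61),
           seq(0.1, 0, length.out = 61)[-1], rep(0, 90))
  waves <- matrix(rep(tri, 12), ncol = 12)
  avg <- make_avg(waves)
  del <- delineate_pwave(avg)
  lf <- local_features(avg, "II", del)
  expect_equal(unname(lf["area"]), 6.0, tolerance = 0.15)
  expect_equal(unname(lf["amplitude"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(lf["peaks"]), 1)
  # uniform amplitude profile -> histogram entropy ln(22)
  ramp <- seq(0, 1, length.out = 220)
  expect_equal(pwavebrs:::hist_entropy(ramp, 22L), log(22), tolerance = 1e-6)
  # constant signal: entropy 0, no peaks, sample entropy flagged 0
  const <- make_avg(matrix(0.1, 300, 12))
  delc <- delineate_pwave(const)
  lfc <- local_features(const, "V3", delc)
  expect_equal(unname(lfc["entropy"]), 0)
  expect_equal(unname(lfc["sampen"]), 0)
  expect_equal(unname(lfc["peaks"]), 0)
  expect_true(attr(lfc, "flat"))
})

test_that("gain scaling: area/amplitude/ptfv1 scale, entropies and widths do not", {
  cs <- clean_subject()
  avg <- epoch_to_averaged_pwave(cs$epochs[[1]])
  avg3 <- avg
  avg3$waves <- 3 * avg$waves
  f1 <- extract_features(avg, 50, 1)
  f3 <- extract_features(avg3, 50, 1)
  for (nm in c("duration_ms", "pr_ms", "fwhm_ms", "axis_deg",
               "entropy_II", "sampen_II", "peaks_II"))
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
  for (nm in c("area_II", "amplitude_II", "ptfv1_au"))
    expect_equal(f3[[nm]], 3 * f1[[nm]], tolerance = 1e-6, label = nm)
})

test_that("the schema fixes 5 + 60 + 2 = 67 features and assembly enforces it", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 67)
  expect_equal(sum(sch$group == "global"), 5)
  expect_equal(sum(sch$group == "local"), 60)
  expect_equal(length(unique(sch$lead[sch$group == "local"])), 12)
  cs <- clean_subject()
  fv <- extract_features(epoch_to_averaged_pwave(cs$epochs[[1]]), 50, 1)
  expect_length(fv, 67)
  expect_identical(names(fv), sch$name)
  expect_false(anyNA(fv))
  # incomplete parts are refused
  expect_error(assemble_feature_vector(fv[1:4], fv[6:65], 50, 1), "schema")
})

test_that("duration, PR and terminal force recover generator ground truth on clean data", {
  cs <- clean_subject()
  fv <- extract_features(epoch_to_averaged_pwave(cs$epochs[[1]]), 50, 1)
  truth <- cs$subject$morphology
  expect_lt(abs(fv[["duration_ms"]] - truth$p_duration_ms), 5)
  expect_lt(abs(fv[["pr_ms"]] - truth$pr_ms), 8)
  expect_lt(abs(fv[["ptfv1_au"]] - cs$subject$tfv1_truth_au), 0.4)
})

test_that("feature error grows with broadband noise", {
  errs <- vapply(c(0, 0.08), function(sdn) {
    nm <- noise_model(mains_amp_mv = 0, wander_amp_mv = 0,
                      broadband_sd_mv = sdn, ectopic_prob = 0)
    s <- generate_recording("NZ", morph = beat_morphology(p_duration_ms = 130,
                                                          pr_ms = 175),
                            duration_s = 30, hr_bpm = 60, rr_sd_s = 0,
                            noise = nm, seed = 11)
    eps <- segment_epochs(preprocess_recording(s$recording))
    fv <- extract_features(epoch_to_averaged_pwave(eps[[1]]), 50, 1)
    abs(fv[["duration_ms"]] - 130)
  }, numeric(1))
  expect_lte(errs[1], errs[2] + 1)  # clean no worse than noisy (1 ms slack)
})
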