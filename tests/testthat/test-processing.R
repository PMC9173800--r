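grid <- trace_grid()

test_that("baseline is the mean of the 20 ms pre-flash window", {
  const <- erg_trace(grid, rep(3.25, length(grid)))
  expect_equal(estimate_baseline(const), 3.25)
  # perturbations confined to t >= 0 leave the baseline untouched
  v <- rep(1, length(grid))
  v[grid >= 0] <- v[grid >= 0] + sin(grid[grid >= 0])
  expect_equal(estimate_baseline(erg_trace(grid, v)), 1)
  # linear drift a + b t: closed-form mean of the line over the window
  a <- 2; b <- 0.3
  drift <- erg_trace(grid, a + b * grid)
  oracle <- a + b * mean(grid[grid >= -20 & grid < 0])
  expect_equal(estimate_baseline(drift), oracle)
  short <- erg_trace(seq(-5, 50, 0.5), numeric(111))
  expect_error(estimate_baseline(short), "20 ms")
})

test_that("artifact rejection removes outlier sweeps but never all", {
  clean <- lapply(1:5, function(i) erg_trace(grid, sin(grid / 10)))
  rr <- reject_artifacts(clean)
  expect_equal(length(rr$kept), 5)
  expect_false(any(rr$log$rejected))

  # a single 2000 uV transient among clean noisy sweeps is removed
  set.seed(11)
  sweeps <- lapply(1:6, function(i)
    erg_trace(grid, sin(grid / 10) + rnorm(length(grid), 0, 3)))
  bad <- sweeps[[4]]
  bad$voltage <- bad$voltage + 2000 * exp(-((grid - 40) / 5)^2)
  sweeps[[4]] <- bad
  rr2 <- reject_artifacts(sweeps)
  expect_equal(which(rr2$log$rejected), 4L)
  expect_equal(length(rr2$kept), 5)

  # degenerate case: everything over the cap keeps the single best sweep
  wild <- lapply(1:4, function(i)
    erg_trace(grid, 3000 * sin(grid / (2 + i))))
  rr3 <- reject_artifacts(wild)
  expect_equal(length(rr3$kept), 1)
  expect_true(rr3$all_failed)
  expect_error(reject_artifacts(list()), "sweep")
})

test_that("averaging is pointwise and shrinks noise like 1/sqrt(n)", {
  tr <- erg_trace(grid, sin(grid / 8))
  expect_equal(average_traces(list(tr)), tr)
  neg <- erg_trace(grid, -tr$voltage)
  expect_equal(average_traces(list(tr, neg))$voltage,
               numeric(length(grid)))
  set.seed(21)
  noisy <- function(n) lapply(seq_len(n), function(i) add_noise(tr, 4))
  res4 <- average_traces(noisy(4))$voltage - tr$voltage
  res64 <- average_traces(noisy(64))$voltage - tr$voltage
  expect_equal(stats::sd(res4) / stats::sd(res64), 4, tolerance = 0.35)
  other <- erg_trace(seq(-20, 100, 0.5), numeric(241))
  expect_error(average_traces(list(tr, other)), "grids differ")
})

test_that("a- and b-wave measurement follow the stated conventions", {
  flat <- erg_trace(grid, numeric(length(grid)))
  aw <- measure_a_wave(flat, 0)
  expect_equal(aw$amplitude, 0)
  expect_equal(aw$peak_time, 3)       # earliest sample wins ties
  # trough -150 with baseline 0 reports +150
  v <- -150 * exp(-((grid - 15) / 4)^2)
  expect_equal(measure_a_wave(erg_trace(grid, v), 0)$amplitude, 150,
               tolerance = 1e-6)
  # b-wave: pure positive kernel, no a-wave -> peak minus baseline
  vb <- bipolar_kernel(grid, 80, 40, 4, "on")
  bw <- measure_b_wave(erg_trace(grid, vb), 0, has_a_wave = FALSE)
  expect_equal(bw$amplitude, 80, tolerance = 1e-6)
  expect_equal(bw$peak_time, 40, tolerance = 0.5)
  # trough-to-peak arithmetic: trough -20 then peak +80 gives 100
  v2 <- -20 * exp(-((grid - 15) / 3)^2) + 80 * exp(-((grid - 45) / 6)^2)
  bw2 <- measure_b_wave(erg_trace(grid, v2), 0)
  expect_equal(bw2$amplitude, 100, tolerance = 0.1)
  expect_error(measure_a_wave(flat, 0, window = c(300, 400)), "window")
  expect_error(measure_b_wave(flat, 0, b_window = c(80, 10)), "ordered")
})

test_that("flicker amplitude is mean peak-to-trough over full cycles", {
  tt <- seq(-20, 250, 0.1)
  pure <- erg_trace(tt, 7 * sin(2 * pi * 30 * tt / 1000))
  expect_equal(measure_flicker_amplitude(pure), 14, tolerance = 1e-3)
  expect_equal(measure_flicker_amplitude(erg_trace(tt, numeric(length(tt)))),
               0)
  short <- erg_trace(seq(0, 60, 0.5), numeric(121))
  expect_error(measure_flicker_amplitude(short), "cycles")
  # round trip through the generator within 1%
  g <- default_gains()
  stim <- standard_protocol()[["LA 30Hz"]]
  tr <- synthesize_flicker_response(stim, g)
  s <- ergdose:::component_setup(stim, g, "none", 1)
  expected <- g$flicker_gain * s$cone_factor *
    (0.25 * g$cone_pr_max +
       g$on_bipolar_gain * g$cone_pii_weight * s$dr_cone_on +
       g$off_bipolar_gain * (s$dr_off_neg + g$off_pos_weight * s$dr_off_pos))
  expect_equal(measure_flicker_amplitude(tr), expected, tolerance = 0.01)
})

test_that("rod isolation by subtraction recovers the rod sub-traces", {
  g <- default_gains()
  prot <- standard_protocol("xenon")
  dark <- synthesize_flash_response(prot[["X4-dark"]], g)
  blue <- synthesize_flash_response(prot[["X4-blue"]], g)
  dark$trace$meta$flash_strength <- 4
  blue$trace$meta$flash_strength <- 4
  iso <- isolate_rod_response(dark$trace, blue$trace)
  rod_true <- dark$components$rod_pr$voltage +
    dark$components$rod_on$voltage + dark$components$op$voltage
  expect_equal(iso$voltage, rod_true, tolerance = 1e-12)
  # identical traces give the zero trace
  z <- isolate_rod_response(dark$trace, dark$trace)
  expect_true(all(z$voltage == 0))
  # flash-strength mismatch is rejected
  d13 <- synthesize_flash_response(prot[["X13-dark"]], g)$trace
  d13$meta$flash_strength <- 13
  expect_error(isolate_rod_response(d13, blue$trace), "flash strengths")
  # noise propagation: residual variance ~ 2 sigma^2
  set.seed(31)
  sigma <- 4
  resid <- replicate(200, {
    nd <- add_noise(dark$trace, sigma)
    nb <- add_noise(blue$trace, sigma)
    isolate_rod_response(nd, nb)$voltage[101] - rod_true[101]
  })
  expect_equal(stats::var(resid), 2 * sigma^2, tolerance = 0.25)
})

test_that("subtraction commutes with sweep averaging", {
  g <- default_gains()
  prot <- standard_protocol("xenon")
  dark <- synthesize_flash_response(prot[["X13-dark"]], g)$trace
  blue <- synthesize_flash_response(prot[["X13-blue"]], g)$trace
  dark$meta$flash_strength <- blue$meta$flash_strength <- 13
  set.seed(41)
  darks <- lapply(1:4, function(i) add_noise(dark, 5))
  blues <- lapply(1:4, function(i) add_noise(blue, 5))
  avg_then_sub <- isolate_rod_response(average_traces(darks),
                                       average_traces(blues))$voltage
  subs <- mapply(function(d, b) isolate_rod_response(d, b)$voltage,
                 darks, blues)
  sub_then_avg <- rowMeans(subs)
  expect_equal(avg_then_sub, sub_then_avg, tolerance = 1e-12)
})

test_that("session features match single-eye truth for noiseless eyes", {
  spec0 <- cohort_spec(n_pairs = 1, noise_sd = 0, drift_sd = 0, eye_sd = 0,
                       artifact_rate = 0, n_sweeps = 2, seed = 3)
  co <- simulate_cohort(spec0)
  prot <- standard_protocol("all")
  sess <- simulate_session(co$subjects[1, ], co$gains[[1]], prot, spec0,
                           seed = 17)
  ef <- extract_features(sess, prot)
  g <- co$gains[[1]]
  # single-eye oracle for the DA 3 a-wave
  tr <- synthesize_flash_response(prot[["DA 3"]], g)$trace
  truth <- measure_a_wave(tr, estimate_baseline(tr))$amplitude
  got <- ef$features$value[ef$features$parameter == "DA 3 a-wave"]
  expect_equal(got, truth, tolerance = 1e-9)
  # feature table covers all stimuli plus rod-isolated rows
  expect_true(all(sprintf("X%g-rod a-wave", xenon_strengths()) %in%
                    ef$features$parameter))
  # DA 0.01 reports no a-wave
  expect_false("DA 0.01 a-wave" %in% ef$features$parameter)
  expect_true("DA 0.01 b-wave" %in% ef$features$parameter)
})

test_that("feature estimates converge to clean values as sweeps grow", {
  prot <- standard_protocol("iscev")["DA 3"]
  clean_spec <- cohort_spec(n_pairs = 1, noise_sd = 0, drift_sd = 0,
                            eye_sd = 0, artifact_rate = 0, n_sweeps = 1,
                            seed = 13)
  co <- simulate_cohort(clean_spec)
  sess_c <- simulate_session(co$subjects[1, ], co$gains[[1]], prot,
                             clean_spec, seed = 2)
  clean_val <- extract_features(sess_c, prot)$features$value[1]
  noisy_spec <- cohort_spec(n_pairs = 1, noise_sd = 10, drift_sd = 4,
                            eye_sd = 0, artifact_rate = 0.2, n_sweeps = 24,
                            artifact_amp = 2000, seed = 13)
  sess_n <- simulate_session(co$subjects[1, ], co$gains[[1]], prot,
                             noisy_spec, seed = 2)
  ef <- extract_features(sess_n, prot)
  noisy_val <- ef$features$value[ef$features$parameter == "DA 3 a-wave"]
  expect_equal(noisy_val, clean_val, tolerance = 0.05)
  # contaminated sweeps were actually rejected
  expect_gt(sum(ef$rejection_log$rejected), 0)
})
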