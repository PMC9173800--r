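protocol <- standard_protocol("all")

test_that("flash synthesis decomposes exactly into its components", {
  g <- default_gains()
  for (label in c("DA 3", "LA 3", "X67-dark", "X67-blue")) {
    for (les in c("none", "crao", "ccsnb")) {
      r <- synthesize_flash_response(protocol[[label]], g, lesion = les)
      comp_sum <- Reduce(`+`, lapply(r$components, `[[`, "voltage"))
      expect_equal(max(abs(r$trace$voltage - comp_sum)), 0)
    }
  }
})

test_that("CRAO leaves only the photoreceptor components", {
  g <- default_gains()
  r <- synthesize_flash_response(protocol[["DA 10"]], g, lesion = "crao")
  pr_sum <- r$components$rod_pr$voltage + r$components$cone_pr$voltage
  expect_equal(r$trace$voltage, pr_sum)
  for (nm in c("rod_on", "cone_on", "cone_off", "op")) {
    expect_true(all(r$components[[nm]]$voltage == 0))
  }
})

test_that("idealized blue background zeroes the rod pathway bit-exactly", {
  g <- default_gains()
  blue <- synthesize_flash_response(protocol[["X13-blue"]], g)
  for (nm in c("rod_pr", "rod_on", "op")) {
    expect_true(all(blue$components[[nm]]$voltage == 0))
  }
  # identical to computing with rod gains set to zero in the dark
  g0 <- g
  g0$rod_pr_max <- 0; g0$rod_pii_weight <- 0; g0$op_gain <- 0
  dark0 <- synthesize_flash_response(protocol[["X13-dark"]], g0)
  expect_identical(blue$trace$voltage, dark0$trace$voltage)
})

test_that("partial rod suppression leaves a scaled rod contribution", {
  g <- default_gains()
  full <- synthesize_flash_response(protocol[["X4-dark"]], g)
  part <- synthesize_flash_response(protocol[["X4-blue"]], g,
                                    rod_suppression = 0.8)
  expect_equal(part$components$rod_pr$voltage,
               0.2 * full$components$rod_pr$voltage)
})

test_that("lesion nesting: silencing OFF in a cCSNB retina gives CRAO", {
  g <- default_gains()
  for (label in c("DA 3", "X67-blue", "LA 3")) {
    crao <- synthesize_flash_response(protocol[[label]], g, lesion = "crao")
    g2 <- apply_lesion(g, "ccsnb")
    g2$off_bipolar_gain <- 0
    manual <- synthesize_flash_response(protocol[[label]], g2)
    expect_identical(crao$trace$voltage, manual$trace$voltage)
    # crao equals ccsnb minus the OFF (and OP) components
    ccsnb <- synthesize_flash_response(protocol[[label]], g,
                                       lesion = "ccsnb")
    expect_equal(crao$trace$voltage,
                 ccsnb$trace$voltage - ccsnb$components$cone_off$voltage -
                   ccsnb$components$op$voltage,
                 tolerance = 1e-12)
  }
})

test_that("a-wave trough magnitude is nondecreasing in flash strength", {
  g <- default_gains()
  strengths <- c(0.01, 0.67, 3, 4, 10, 13, 67)
  troughs <- vapply(strengths, function(s) {
    stim <- stimulus_spec(sprintf("I%g", s), s, "dark")
    tr <- synthesize_flash_response(stim, g)$trace
    -measure_a_wave(tr, estimate_baseline(tr))$trough
  }, 0)
  expect_true(all(diff(troughs) >= -1e-9))
})

test_that("flicker response is periodic, cone-driven, and OFF-resilient", {
  g <- default_gains()
  stim <- protocol[["LA 30Hz"]]
  tr <- synthesize_flicker_response(stim, g)
  per <- 1000 / 30
  # steady-state periodicity: v(t) = v(t + period) sample by sample
  tgrid <- seq(40, 150, by = 0.37)
  v1 <- synthesize_flicker_response(stim, g, time = tgrid)$voltage
  v2 <- synthesize_flicker_response(stim, g, time = tgrid + per)$voltage
  expect_lt(max(abs(v1 - v2)), 1e-9)
  # all cone gains zero -> flat
  g0 <- g
  g0$cone_pr_max <- 0; g0$cone_pii_weight <- 0; g0$off_bipolar_gain <- 0
  expect_true(all(synthesize_flicker_response(stim, g0)$voltage == 0))
  # ccsnb reduces but does not abolish the flicker (OFF path intact)
  a_none <- measure_flicker_amplitude(tr)
  a_cs <- measure_flicker_amplitude(
    synthesize_flicker_response(stim, g, lesion = "ccsnb"))
  expect_lt(a_cs, a_none)
  expect_gt(a_cs, 0.05 * a_none)
  # mode guards
  expect_error(synthesize_flicker_response(protocol[["DA 3"]], g),
               "single-flash")
  expect_error(synthesize_flash_response(stim, g), "flicker")
})

test_that("the LA-flash gradient notch appears when OFF weight drops", {
  # waveform-shape signature near 25 ms: with the full OFF complement the
  # rising limb is smooth (gradient stays positive across 18-32 ms); with
  # the OFF gain reduced a gradient change (local dip) emerges there
  g <- default_gains()
  min_grad <- function(off_scale) {
    gg <- g
    gg$off_bipolar_gain <- gg$off_bipolar_gain * off_scale
    tr <- synthesize_flash_response(protocol[["LA 3"]], gg)$trace
    dv <- diff(tr$voltage) / diff(tr$time)
    tm <- (tr$time[-1] + tr$time[-length(tr$time)]) / 2
    min(dv[tm >= 18 & tm <= 32])
  }
  expect_gt(min_grad(1), 0)
  expect_lt(min_grad(0.4), 0)
  expect_lt(min_grad(0.3), min_grad(1))
})

test_that("add_noise is reproducible and calibrated", {
  tr <- synthesize_flash_response(protocol[["DA 3"]], default_gains())$trace
  expect_identical(add_noise(tr, 0, 0)$voltage, tr$voltage)
  n1 <- add_noise(tr, 5, 2, seed = 42)
  n2 <- add_noise(tr, 5, 2, seed = 42)
  expect_identical(n1$voltage, n2$voltage)
  expect_error(add_noise(tr, -1), ">= 0")
  # law of large numbers: sample variance of the added noise ~ sd^2
  long <- erg_trace(seq(-20, 49979.5, by = 0.5), numeric(100000))
  noisy <- add_noise(long, 3, 0, seed = 7)
  expect_equal(stats::var(noisy$voltage), 9, tolerance = 0.02)
})

test_that("trace container enforces a uniform grid", {
  expect_error(erg_trace(c(0, 1, 3), c(0, 0, 0)), "uniform")
  expect_error(erg_trace(1:3, 1:4), "lengths")
  tr <- erg_trace(seq(-20, 50, 0.5), numeric(141), list(stimulus = "x"))
  expect_s3_class(tr, "erg_trace")
})
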