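# Phase-contrast flow: per-frame flow, averages, retrograde decomposition
# and area pulsatility.

uniform_frame <- function(v, nmask = 100, grid = 20) {
  mask <- matrix(FALSE, grid, grid)
  mask[seq_len(nmask)] <- TRUE
  list(velocity = matrix(v, grid, grid), mask = mask)
}

test_that("frame flow is velocity x area summed over the ROI", {
  f <- uniform_frame(10, nmask = 100)          # 100 px x 0.04 cm^2 = 4 cm^2
  expect_equal(frame_flow(f$velocity, f$mask, 0.04), 40)
  z <- uniform_frame(0)
  expect_equal(frame_flow(z$velocity, z$mask, 0.04), 0)
  expect_error(frame_flow(f$velocity, matrix(FALSE, 20, 20), 0.04),
               class = "rhcmr_empty_roi")
})

test_that("parabolic profile integrates to half the peak times the area", {
  grid <- 201; R <- 90; vmax <- 120
  ctr <- (grid + 1) / 2
  px <- matrix(rep(seq_len(grid), grid), grid); py <- t(px)
  r <- sqrt((px - ctr)^2 + (py - ctr)^2)
  mask <- r <= R
  v <- matrix(0, grid, grid)
  v[mask] <- vmax * (1 - (r[mask] / R)^2)
  pa <- 0.01
  flow <- frame_flow(v, mask, pa)
  area <- sum(mask) * pa
  expect_lt(abs(flow - vmax / 2 * area) / (vmax / 2 * area), 0.02)
})

test_that("average velocity is the mean of per-frame masked means", {
  s <- velocity_series(list(uniform_frame(10), uniform_frame(10)),
                       0.04, 1, 2)
  expect_equal(average_velocity(s), 10)
  s2 <- velocity_series(list(uniform_frame(10), uniform_frame(-10)),
                        0.04, 1, 2)
  expect_equal(average_velocity(s2), 0)
})

test_that("velocity phantom hits a programmed cycle-average velocity", {
  ph <- make_velocity_phantom(mean_velocity = 7.6)
  expect_equal(average_velocity(ph$series), 7.6, tolerance = 0.1 / 7.6)
})

test_that("retrograde metrics follow the per-beat volume arithmetic", {
  # no negative velocities anywhere -> (0, 0)
  ph0 <- make_velocity_phantom(retrograde_fraction = 0)
  expect_equal(unname(retrograde_metrics(ph0$series)), c(0, 0))

  # 80 mL/beat antegrade, 8 mL retrograde, RR 1 s, BSA 2
  ph <- make_velocity_phantom(antegrade_ml_per_beat = 80,
                              retrograde_fraction = 0.1, rr = 1, bsa = 2)
  rm <- retrograde_metrics(ph$series)
  expect_equal(rm[["retrograde_flow_index"]], 0.24, tolerance = 1e-9)
  expect_equal(rm[["retrograde_percent"]], 10, tolerance = 1e-9)

  # phantom tuned to the 0.3 L/min/m^2 operating point
  ph3 <- make_velocity_phantom(antegrade_ml_per_beat = 80,
                               retrograde_fraction = 0.125, rr = 1, bsa = 2)
  expect_equal(retrograde_metrics(ph3$series)[["retrograde_flow_index"]],
               0.30, tolerance = 0.01 / 0.3)
})

test_that("net flow decomposes exactly into antegrade minus retrograde", {
  set.seed(9)
  for (i in 1:10) {
    ph <- make_velocity_phantom(
      antegrade_ml_per_beat = runif(1, 40, 120),
      retrograde_fraction = runif(1, 0, 0.4),
      rr = runif(1, 0.6, 1.2), bsa = runif(1, 1.4, 2.2))
    s <- ph$series
    dt <- s$rr_interval / length(s$frames)
    net <- sum(vapply(s$frames, function(f) {
      frame_flow(f$velocity, f$mask, s$pixel_area)
    }, numeric(1))) * dt
    bv <- rhcmr:::beat_volumes(s)
    expect_equal(net, bv[["antegrade"]] - bv[["retrograde"]],
                 tolerance = 1e-10)
    expect_equal(bv[["antegrade"]], ph$truth$antegrade_ml, tolerance = 1e-9)
  }
})

test_that("retrograde index scales with heart rate and inversely with BSA", {
  base <- make_velocity_phantom(retrograde_fraction = 0.1, rr = 1, bsa = 2)
  slower <- make_velocity_phantom(retrograde_fraction = 0.1, rr = 2, bsa = 2)
  bigger <- make_velocity_phantom(retrograde_fraction = 0.1, rr = 1, bsa = 1)
  i0 <- retrograde_metrics(base$series)[["retrograde_flow_index"]]
  expect_equal(retrograde_metrics(slower$series)[["retrograde_flow_index"]],
               i0 / 2, tolerance = 1e-9)
  expect_equal(retrograde_metrics(bigger$series)[["retrograde_flow_index"]],
               i0 * 2, tolerance = 1e-9)
})

test_that("zero antegrade volume leaves the percentage undefined with a warning", {
  f <- uniform_frame(-5)
  s <- velocity_series(list(f, f), 0.04, 1, 2)
  expect_warning(rm <- retrograde_metrics(s), "undefined")
  expect_true(is.na(rm[["retrograde_percent"]]))
  expect_gt(rm[["retrograde_flow_index"]], 0)
})

test_that("PA pulsatility uses max/min mask areas with the minimum denominator", {
  mk <- function(npix) uniform_frame(5, nmask = npix)
  s <- velocity_series(list(mk(100), mk(80)), 0.1, 1, 2)   # 10 / 8 cm^2
  ap <- pa_area_pulsatility(s)
  expect_equal(unname(ap), c(10, 8, 25))
  s2 <- velocity_series(list(mk(92), mk(80)), 0.1, 1, 2)   # 9.2 / 8 cm^2
  expect_equal(pa_area_pulsatility(s2)[["pa_rac"]], 15)
  sc <- velocity_series(list(mk(90), mk(90)), 0.1, 1, 2)
  expect_equal(pa_area_pulsatility(sc)[["pa_rac"]], 0)
})

test_that("pa_rac is a pure ratio, invariant to pixel-area rescaling", {
  ph <- make_velocity_phantom(area_pulsatility = 30)
  s <- ph$series
  s_big <- velocity_series(s$frames, s$pixel_area * 3.7, s$rr_interval,
                           s$bsa)
  expect_equal(pa_area_pulsatility(s)[["pa_rac"]],
               pa_area_pulsatility(s_big)[["pa_rac"]])
  # and the phantom's programmed pulsatility is recovered (discretized mask)
  expect_equal(pa_area_pulsatility(s)[["pa_rac"]], 30, tolerance = 0.1)
})

test_that("velocity series round-trips through the CSV bundle", {
  ph <- make_velocity_phantom(n_frames = 4, grid = 12)
  dir <- withr::local_tempdir()
  write_velocity_series(ph$series, dir)
  back <- read_velocity_series(dir)
  expect_equal(flow_metrics(back), flow_metrics(ph$series), tolerance = 1e-9)
})
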