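# Short-axis geometry: polygon areas, slice-summation volumes, phase
# selection, masses and BSA.

test_that("shoelace area is exact on squares and orientation-independent", {
  sq <- square_vertices(10)
  expect_equal(polygon_area(sq), 100)
  expect_equal(polygon_area(sq[4:1, ]), 100)
  # translation must not change the area
  expect_equal(polygon_area(square_vertices(10, centre = c(-50, 120))), 100)
})

test_that("regular polygon area matches the closed form and converges to the circle", {
  # closed form for a regular n-gon of circumradius r: (n/2) r^2 sin(2*pi/n)
  for (n in c(8, 16, 64)) {
    poly <- rhcmr:::regular_polygon(10, 10, n)
    expect_equal(polygon_area(poly), (n / 2) * 100 * sin(2 * pi / n),
                 tolerance = 1e-12)
  }
  a64 <- polygon_area(rhcmr:::regular_polygon(10, 10, 64))
  expect_lt(abs(a64 - pi * 100) / (pi * 100), 0.002)
})

test_that("degenerate and self-intersecting contours are rejected", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))),
               class = "rhcmr_invalid_contour")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(slice_contour("RV_ENDO", 0, 0, bowtie),
               class = "rhcmr_invalid_contour")
})

test_that("stack volume is area x spacing summed over slices", {
  # single slice: A * d exactly
  one <- contour_stack("p", 7.5, list(
    slice_contour("RV_ENDO", 0, 0, square_vertices(20))))
  expect_equal(stack_volume(one, "RV_ENDO", 0), 400 * 7.5 / 1000)

  # 10 identical circular contours, r = 20 mm, spacing 10 mm -> cylinder
  ph <- make_ventricle_phantom(ventricle_phantom_spec(
    "CYLINDER", radius = 20, n_slices = 10, slice_spacing = 10))
  v <- stack_volume(ph$stack, "RV_ENDO", 0)
  expect_lt(abs(v - 125.6637) / 125.6637, 0.003)

  expect_error(stack_volume(one, "LV_ENDO", 0),
               class = "rhcmr_missing_structure")
})

test_that("half-ellipsoid phantom volume converges to (2/3) pi a b c", {
  a <- 25; b <- 20; c_mm <- 80
  ph <- make_ventricle_phantom(ventricle_phantom_spec(
    "HALF_ELLIPSOID", radius = a, semi_axis_b = b,
    n_slices = c_mm, slice_spacing = 1, n_phases = 1,
    vertex_count = 64))
  v <- stack_volume(ph$stack, "RV_ENDO", 0)
  analytic <- (2 / 3) * pi * a * b * c_mm / 1000
  expect_lt(abs(v - analytic) / analytic, 0.01)
  # the generator's own ground truth agrees with its sampled slices
  expect_equal(ph$truth$edv, v, tolerance = 0.002)
})

test_that("ED is phase 0 and ES the volume argmin with earliest-phase ties", {
  expect_equal(select_ed_es_phases(stack_with_phase_volumes(
    c(100, 80, 50, 70)), "RV"),
    c(ed_phase = 0L, es_phase = 2L))
  expect_equal(select_ed_es_phases(stack_with_phase_volumes(
    c(90, 90, 90)), "RV"),
    c(ed_phase = 0L, es_phase = 0L))
  expect_error(select_ed_es_phases(stack_with_phase_volumes(100), "RV"),
               class = "rhcmr_insufficient_phases")
})

test_that("phantom with programmed contraction puts ES at the declared phase", {
  ph <- make_ventricle_phantom(ventricle_phantom_spec(
    "CYLINDER", n_phases = 20, es_phase = 7, systolic_scale = 0.6))
  expect_equal(select_ed_es_phases(ph$stack, "RV"),
               c(ed_phase = 0L, es_phase = 7L))
})

test_that("volumetrics arithmetic is definitional: SV, EF, SVI, mass, VMI", {
  stk <- square_shell_stack(es_scale = 0.5)  # EDV 40 mL, ESV 20 mL
  res <- ventricular_volumetrics(stk, bsa = 2.0)
  expect_equal(res$rv_edv, 40)
  expect_equal(res$rv_sv, res$rv_edv - res$rv_esv)
  expect_equal(res$rv_ef, 100 * res$rv_sv / res$rv_edv)
  expect_equal(res$rv_ef, 50)
  expect_equal(res$rv_svi, res$rv_sv / 2.0)
  # wall cross-section 300 mm^2 x 10 slices x 10 mm = 30 cm^3 -> 31.5 g
  expect_equal(res$rv_mass, 31.5)
  expect_equal(res$lv_mass, 63)
  expect_equal(res$vmi, 0.5)

  expect_error(ventricular_volumetrics(stk, bsa = 0),
               class = "rhcmr_invalid_bsa")
})

test_that("mass equals (epi - endo volume) x 1.05 exactly", {
  stk <- square_shell_stack()
  wall_ml <- stack_volume(stk, "RV_EPI", 0) - stack_volume(stk, "RV_ENDO", 0)
  res <- ventricular_volumetrics(stk, bsa = 1.9)
  expect_identical(res$rv_mass, wall_ml * 1.05)
})

test_that("an epicardial contour smaller than its endocardial one is rejected", {
  expect_error(
    contour_stack("bad", 10, list(
      slice_contour("RV_ENDO", 0, 0, square_vertices(20)),
      slice_contour("RV_EPI", 0, 0, square_vertices(10)))),
    class = "rhcmr_inconsistent_contour")
})

test_that("volumes and masses are invariant under rigid motion", {
  stk <- square_shell_stack(n_slices = 4)
  set.seed(31)
  for (i in 1:5) {
    moved <- rigid_transform_stack(stk, runif(1, 0, 2 * pi),
                                   runif(2, -80, 80))
    expect_equal(ventricular_volumetrics(moved, 1.9)[c("rv_edv", "rv_esv",
                                                       "rv_mass", "lv_mass")],
                 ventricular_volumetrics(stk, 1.9)[c("rv_edv", "rv_esv",
                                                     "rv_mass", "lv_mass")],
                 tolerance = 1e-10)
  }
})

test_that("Du Bois BSA evaluates correctly and scales as a power law", {
  expect_equal(bsa_from_height_weight(180, 75),
               0.007184 * 180^0.725 * 75^0.425)
  expect_equal(round(bsa_from_height_weight(180, 75), 2), 1.94)
  expect_error(bsa_from_height_weight(0, 75),
               class = "rhcmr_invalid_anthropometry")
  expect_equal(bsa_from_height_weight(170, 140) /
                 bsa_from_height_weight(170, 70), 2^0.425)
})
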