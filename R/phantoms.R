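# Analytic phantoms: polygonized ventricle stacks and discretized velocity
# series whose ground truth is known in closed form, so the extraction code
# can be validated end-to-end without images.

#' Specification of a ventricle phantom
#'
#' Shapes: `"CYLINDER"` (constant circular cavity), `"HALF_ELLIPSOID"`
#' (cavity area tapering to the apex as an ellipsoid cap, sampled at slice
#' midpoints), `"SHELL"` (cylindrical cavity plus a concentric wall of
#' constant thickness, giving epicardial contours and a closed-form mass).
#' Contraction over the cine cycle scales every cavity area by a smooth
#' factor reaching `systolic_scale` at `es_phase`, so the ejection fraction
#' is exactly `100 * (1 - systolic_scale)`.
#'
#' @param shape `"CYLINDER"`, `"HALF_ELLIPSOID"` or `"SHELL"`.
#' @param radius cavity radius, mm (in-plane semi-axis `a` for the
#'   half-ellipsoid).
#' @param semi_axis_b second in-plane semi-axis, mm (half-ellipsoid only;
#'   defaults to `radius`).
#' @param wall_thickness wall thickness, mm (shell only).
#' @param n_slices number of short-axis slices.
#' @param slice_spacing inter-slice distance, mm.
#' @param n_phases cine phases per cycle.
#' @param systolic_scale end-systolic cavity area as a fraction of
#'   end-diastolic (in (0, 1]).
#' @param es_phase phase index of end-systole (default roughly one third
#'   of the cycle).
#' @param vertex_count polygon vertices per contour.
#' @return an object of class `ventricle_phantom_spec`.
#' @export
ventricle_phantom_spec <- function(shape = c("CYLINDER", "HALF_ELLIPSOID",
                                             "SHELL"),
                                   radius = 20, semi_axis_b = NULL,
                                   wall_thickness = 5, n_slices = 10,
                                   slice_spacing = 10, n_phases = 20,
                                   systolic_scale = 0.5, es_phase = NULL,
                                   vertex_count = 64) {
  shape <- match.arg(shape)
  stopifnot(radius > 0, wall_thickness > 0, n_slices >= 1,
            slice_spacing > 0, n_phases >= 1, systolic_scale > 0,
            systolic_scale <= 1, vertex_count >= 3)
  es_phase <- as.integer(es_phase %||%
                           min(n_phases - 1, max(1, round(n_phases / 3))))
  stopifnot(es_phase >= 0, es_phase < n_phases)
  structure(list(shape = shape, radius = radius,
                 semi_axis_b = semi_axis_b %||% radius,
                 wall_thickness = wall_thickness, n_slices = n_slices,
                 slice_spacing = slice_spacing, n_phases = n_phases,
                 systolic_scale = systolic_scale, es_phase = es_phase,
                 vertex_count = vertex_count),
            class = "ventricle_phantom_spec")
}

# smooth area-scale factor over the cycle: 1 at phase 0, `ss` exactly at
# phase e, back towards 1 at the end of the cycle; unique minimum at e.
phase_scale <- function(phase, n_phases, es_phase, ss) {
  if (n_phases == 1) return(rep(1, length(phase)))
  w <- ifelse(phase <= es_phase,
              (1 - cos(pi * phase / max(es_phase, 1))) / 2,
              (1 + cos(pi * (phase - es_phase) / (n_phases - es_phase))) / 2)
  1 + (ss - 1) * w
}

regular_polygon <- function(rx, ry, n) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(rx * cos(th), ry * sin(th))
}

#' Generate a polygonized ventricle phantom with analytic ground truth
#'
#' Emits RV endocardial contours on every slice and phase, plus (for the
#' shell shape) RV/LV epi- and endocardial contours at end-diastole so
#' masses and VMI can be computed.  The LV of the shell phantom is a second
#' concentric shell with twice the wall cross-section, giving a VMI of 0.5
#' before polygonization.  Ground truth uses the closed forms of the
#' continuous shapes sampled exactly as the slice-summation method samples
#' them, so the only discrepancy left is polygonal area error.
#'
#' @param spec a [ventricle_phantom_spec()].
#' @return list with elements `stack` (a [contour_stack()]) and `truth`
#'   (list: `edv`, `esv`, `sv` in mL, `ef` percent, `es_phase`, and for the
#'   shell `rv_mass`, `lv_mass` in g and `vmi`).
#' @export
#' @examples
#' ph <- make_ventricle_phantom(ventricle_phantom_spec("CYLINDER"))
#' ph$truth$edv  # ~125.7 mL for r = 20 mm, 10 slices, 10 mm spacing
make_ventricle_phantom <- function(spec) {
  stopifnot(inherits(spec, "ventricle_phantom_spec"))
  n <- spec$n_slices; d <- spec$slice_spacing; nv <- spec$vertex_count
  a <- spec$radius; b <- spec$semi_axis_b

  # per-slice in-plane semi-axes of the end-diastolic cavity
  slice_axes <- switch(spec$shape,
    CYLINDER = , SHELL = {
      lapply(seq_len(n) - 1, function(i) c(a, b))
    },
    HALF_ELLIPSOID = {
      # slice midpoints along the long axis c = n * d (base at z = 0)
      cz <- n * d
      lapply(seq_len(n) - 1, function(i) {
        z <- (i + 0.5) * d
        f <- sqrt(max(0, 1 - (z / cz)^2))
        c(a * f, b * f)
      })
    })

  contours <- list()
  for (ph in seq_len(spec$n_phases) - 1) {
    s <- phase_scale(ph, spec$n_phases, spec$es_phase, spec$systolic_scale)
    rs <- sqrt(s)  # areas scale by s => linear dimensions by sqrt(s)
    for (i in seq_len(n) - 1) {
      ax <- slice_axes[[i + 1]]
      if (ax[1] <= 0 || ax[2] <= 0) next
      contours[[length(contours) + 1]] <-
        slice_contour("RV_ENDO", i, ph,
                      regular_polygon(ax[1] * rs, ax[2] * rs, nv))
    }
  }

  # polygonal areas underestimate the ellipse; ground truth matches the
  # continuous shape, convergence is the geometry module's property
  ellipse_area <- function(ax) pi * ax[1] * ax[2]
  edv <- sum(vapply(slice_axes, ellipse_area, numeric(1))) * d / MM3_PER_ML
  esv <- edv * spec$systolic_scale
  truth <- list(edv = edv, esv = esv, sv = edv - esv,
                ef = 100 * (1 - spec$systolic_scale),
                es_phase = spec$es_phase)

  if (spec$shape == "SHELL") {
    t_rv <- spec$wall_thickness
    # LV: concentric shell centred away from the RV, wall sized for twice
    # the RV wall cross-section => closed-form VMI 0.5
    rv_wall_area <- pi * ((a + t_rv)^2 - a^2)
    lv_r <- a
    lv_R <- sqrt(lv_r^2 + 2 * rv_wall_area / pi)
    off <- 4 * (a + t_rv)  # keep the two shells disjoint in-plane
    for (i in seq_len(n) - 1) {
      contours[[length(contours) + 1]] <-
        slice_contour("RV_EPI", i, 0L,
                      regular_polygon(a + t_rv, b + t_rv, nv))
      lv_endo <- regular_polygon(lv_r, lv_r, nv)
      lv_epi <- regular_polygon(lv_R, lv_R, nv)
      lv_endo[, 1] <- lv_endo[, 1] + off
      lv_epi[, 1] <- lv_epi[, 1] + off
      contours[[length(contours) + 1]] <- slice_contour("LV_ENDO", i, 0L, lv_endo)
      contours[[length(contours) + 1]] <- slice_contour("LV_EPI", i, 0L, lv_epi)
    }
    rv_mass <- (pi * ((a + t_rv) * (b + t_rv) - a * b)) * n * d /
      MM3_PER_ML * MYOCARDIAL_DENSITY_G_PER_CM3
    lv_mass <- (pi * (lv_R^2 - lv_r^2)) * n * d / MM3_PER_ML *
      MYOCARDIAL_DENSITY_G_PER_CM3
    truth$rv_mass <- rv_mass
    truth$lv_mass <- lv_mass
    truth$vmi <- rv_mass / lv_mass
  }

  list(stack = contour_stack("phantom", d, contours,
                             n_slices = n, n_phases = spec$n_phases),
       truth = truth)
}

#' Generate a discretized velocity-map phantom with known flow volumes
#'
#' Systolic frames carry a parabolic (Poiseuille-like) antegrade profile
#' over a circular region; diastolic frames carry a uniform retrograde
#' patch over a sub-region.  After discretization the velocities are
#' rescaled so the per-beat antegrade and retrograde volumes match the
#' requested values exactly; the returned ground truth records the
#' resulting flow indices.  The mask radius can pulse between a systolic
#' maximum and diastolic minimum to give a known area pulsatility.
#'
#' @param antegrade_ml_per_beat forward volume per beat, mL.
#' @param retrograde_fraction retrograde volume as a fraction of the
#'   antegrade volume (>= 0).
#' @param rr cardiac cycle length, s.
#' @param bsa body surface area, m^2.
#' @param n_frames frames per cycle.
#' @param grid matrix dimension (pixels per side).
#' @param pixel_area pixel area, cm^2.
#' @param mask_radius_frac mask radius at diastole, as a fraction of the
#'   half-grid; the systolic radius is `mask_radius_frac * sqrt(1 +
#'   area_pulsatility/100)`.
#' @param area_pulsatility target PA relative area change, percent
#'   (max-min over min area); 0 keeps the mask fixed.
#' @param mean_velocity optional target cycle-average velocity, cm/s; when
#'   given, all velocities are rescaled to hit it (flow volumes rescale by
#'   the same factor, recorded in the ground truth).
#' @param noise_sd optional Gaussian pixel noise SD, cm/s, added outside
#'   the rescaling (defaults to 0: exact volumes).
#' @param seed integer seed for the noise.
#' @return list with `series` (a [velocity_series()]) and `truth` (list:
#'   `antegrade_ml`, `retrograde_ml`, `retrograde_flow_index`,
#'   `retrograde_percent`, `mean_velocity`, `systolic_area`,
#'   `diastolic_area`, `pa_rac`).
#' @export
make_velocity_phantom <- function(antegrade_ml_per_beat = 80,
                                  retrograde_fraction = 0.1,
                                  rr = 1, bsa = 2, n_frames = 20,
                                  grid = 48, pixel_area = 0.04,
                                  mask_radius_frac = 0.6,
                                  area_pulsatility = 0,
                                  mean_velocity = NULL,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(antegrade_ml_per_beat > 0, retrograde_fraction >= 0,
            rr > 0, bsa > 0, n_frames >= 2, grid >= 8)
  if (!is.null(seed)) set.seed(seed)
  dt <- rr / n_frames
  n_sys <- max(1L, floor(n_frames / 2))
  ctr <- (grid + 1) / 2
  px <- matrix(rep(seq_len(grid), grid), grid)
  py <- t(px)
  rad <- sqrt((px - ctr)^2 + (py - ctr)^2)  # pixel units

  r_dia <- mask_radius_frac * grid / 2
  r_sys <- r_dia * sqrt(1 + area_pulsatility / 100)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    systole <- f <= n_sys
    rmask <- if (systole) r_sys else r_dia
    mask <- rad <= rmask
    v <- matrix(0, grid, grid)
    if (systole) {
      # parabolic profile, peak 1 at the centre, zero at the mask edge
      v[mask] <- pmax(0, 1 - (rad[mask] / rmask)^2)
    } else if (retrograde_fraction > 0) {
      v[rad <= rmask / 2] <- -1
    }
    frames[[f]] <- list(velocity = v, mask = mask)
  }

  # rescale antegrade and retrograde parts so beat volumes are exact
  raw_ante <- sum(vapply(frames, function(f) {
    sum(pmax(f$velocity[f$mask], 0))
  }, numeric(1))) * pixel_area * dt
  raw_retro <- sum(vapply(frames, function(f) {
    sum(pmax(-f$velocity[f$mask], 0))
  }, numeric(1))) * pixel_area * dt
  k_a <- antegrade_ml_per_beat / raw_ante
  k_r <- if (raw_retro > 0) {
    retrograde_fraction * antegrade_ml_per_beat / raw_retro
  } else 0
  for (f in seq_len(n_frames)) {
    v <- frames[[f]]$velocity
    frames[[f]]$velocity <- pmax(v, 0) * k_a - pmax(-v, 0) * k_r
  }

  ante <- antegrade_ml_per_beat
  retro <- retrograde_fraction * antegrade_ml_per_beat

  if (!is.null(mean_velocity)) {
    cur <- mean(vapply(frames, function(f) mean(f$velocity[f$mask]),
                       numeric(1)))
    if (abs(cur) < .Machine$double.eps) {
      rhcmr_error("cannot scale a zero-mean phantom to a target velocity",
                  "rhcmr_invalid_phantom")
    }
    k <- mean_velocity / cur
    for (f in seq_len(n_frames)) {
      frames[[f]]$velocity <- frames[[f]]$velocity * k
    }
    ante <- ante * k; retro <- retro * k
  }

  if (noise_sd > 0) {
    for (f in seq_len(n_frames)) {
      frames[[f]]$velocity <- frames[[f]]$velocity +
        matrix(rnorm(grid^2, 0, noise_sd), grid)
    }
  }

  series <- velocity_series(frames, pixel_area, rr, bsa)
  areas <- vapply(frames, function(f) sum(f$mask) * pixel_area, numeric(1))
  truth <- list(
    antegrade_ml = ante, retrograde_ml = retro,
    retrograde_flow_index = retro * (60 / rr) / 1000 / bsa,
    retrograde_percent = if (ante > 0) 100 * retro / ante else NA_real_,
    mean_velocity = mean(vapply(frames, function(f) mean(f$velocity[f$mask]),
                                numeric(1))),
    systolic_area = max(areas), diastolic_area = min(areas),
    pa_rac = 100 * (max(areas) - min(areas)) / min(areas))
  list(series = series, truth = truth)
}

#' Generate a synthetic four-chamber landmark pair with known metrics
#'
#' Builds end-diastolic and end-systolic landmark frames whose TAPSE,
#' fractional TAAD, SFD excursion and RV area change equal the programmed
#' values, optionally under a random rigid rotation/translation (the
#' metrics are invariant to it).
#'
#' @param taad_ed_cm end-diastolic annulus-apex distance, cm.
#' @param tapse_cm programmed excursion, cm.
#' @param sfd_ed_cm,sfd_excursion_cm end-diastolic septum-free-wall
#'   distance and its excursion, cm.
#' @param area_ed_cm2 end-diastolic RV area, cm^2.
#' @param rvrac_percent programmed relative area change, percent.
#' @param rotate,translate optional rigid motion: rotation angle (radians)
#'   and length-2 translation (mm) applied to both frames.
#' @return list with `ed` and `es` ([four_chamber_frame()]) and `truth`.
#' @export
make_landmark_phantom <- function(taad_ed_cm = 8, tapse_cm = 2,
                                  sfd_ed_cm = 4, sfd_excursion_cm = 1,
                                  area_ed_cm2 = 10, rvrac_percent = 40,
                                  rotate = 0, translate = c(0, 0)) {
  stopifnot(taad_ed_cm > 0, sfd_ed_cm > 0, area_ed_cm2 > 0)
  rig <- function(p) {
    R <- matrix(c(cos(rotate), sin(rotate), -sin(rotate), cos(rotate)), 2)
    as.numeric(R %*% p + translate)
  }
  apex <- c(0, 0)
  mid <- taad_ed_cm * MM_PER_CM / 2
  frame_at <- function(phase, taad_cm, sfd_cm, area_cm2) {
    four_chamber_frame(
      phase,
      tricuspid_annulus = rig(c(0, taad_cm * MM_PER_CM)),
      rv_apex = rig(apex),
      septal_mid = rig(c(0, mid)),
      freewall_mid = rig(c(sfd_cm * MM_PER_CM, mid)),
      rv_area = area_cm2 * 100)
  }
  ed <- frame_at("ED", taad_ed_cm, sfd_ed_cm, area_ed_cm2)
  es <- frame_at("ES", taad_ed_cm - tapse_cm,
                 sfd_ed_cm - sfd_excursion_cm,
                 area_ed_cm2 * (1 - rvrac_percent / 100))
  list(ed = ed, es = es,
       truth = list(tapse = tapse_cm,
                    f_taad = 100 * tapse_cm / taad_ed_cm,
                    sfd = sfd_excursion_cm,
                    f_sfd = 100 * sfd_excursion_cm / sfd_ed_cm,
                    rvrac = rvrac_percent))
}
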