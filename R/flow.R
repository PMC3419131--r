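# Phase-contrast pulmonary-artery flow: per-frame flow, cycle-average
# velocity, retrograde flow indices and PA area pulsatility from
# velocity-encoded frame series.

#' Velocity-encoded frame series
#'
#' Time-resolved through-plane velocity maps over one cardiac cycle with a
#' pulmonary-artery region mask per frame.  Antegrade flow is positive by
#' sign convention.  Frames are bin averages from retrospective gating, so
#' each frame represents `rr_interval / n_frames` seconds.
#'
#' @param frames list of `list(velocity = <matrix cm/s>, mask = <logical
#'   matrix>)`; all frames must share dimensions and every mask must be
#'   non-empty.
#' @param pixel_area in-plane pixel area, cm^2.
#' @param rr_interval cardiac cycle length, s (> 0).
#' @param bsa body surface area, m^2 (> 0), used for flow indexing.
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(frames, pixel_area, rr_interval, bsa) {
  if (length(frames) < 1) {
    rhcmr_error("need at least one frame", "rhcmr_invalid_series")
  }
  dims <- lapply(frames, function(f) dim(f$velocity))
  if (any(!vapply(dims, identical, logical(1), dims[[1]]))) {
    rhcmr_error("all velocity maps must share dimensions",
                "rhcmr_invalid_series")
  }
  for (f in frames) {
    if (!identical(dim(f$mask), dim(f$velocity))) {
      rhcmr_error("mask and velocity map dimensions differ",
                  "rhcmr_invalid_series")
    }
    if (!any(f$mask)) {
      rhcmr_error("pulmonary-artery mask is empty in a frame",
                  "rhcmr_empty_roi")
    }
  }
  stopifnot(pixel_area > 0, rr_interval > 0, bsa > 0)
  structure(list(frames = frames, pixel_area = pixel_area,
                 rr_interval = rr_interval, bsa = bsa),
            class = "velocity_series")
}

#' Instantaneous flow through the masked region of one frame
#'
#' Sum over masked pixels of velocity x pixel area: cm/s x cm^2 = cm^3/s =
#' mL/s.  Antegrade (positive) and retrograde (negative) pixels partially
#' cancel; see [retrograde_metrics()] for the signed decomposition.
#'
#' @param velocity_map numeric matrix, cm/s.
#' @param pa_mask logical matrix of the same dimensions.
#' @param pixel_area pixel area, cm^2.
#' @return flow in mL/s.
#' @export
frame_flow <- function(velocity_map, pa_mask, pixel_area) {
  if (!any(pa_mask)) {
    rhcmr_error("pulmonary-artery mask is empty", "rhcmr_empty_roi")
  }
  sum(velocity_map[pa_mask]) * pixel_area
}

#' Cycle-average pulmonary-artery velocity
#'
#' Mean over frames of the mean masked velocity per frame, cm/s.
#'
#' @param series a [velocity_series()].
#' @return cm/s.
#' @export
average_velocity <- function(series) {
  mean(vapply(series$frames, function(f) mean(f$velocity[f$mask]),
              numeric(1)))
}

# antegrade / retrograde volume per beat (mL each), frame-duration weighted
beat_volumes <- function(series) {
  dt <- series$rr_interval / length(series$frames)
  ante <- retro <- 0
  for (f in series$frames) {
    v <- f$velocity[f$mask]
    ante <- ante + sum(pmax(v, 0)) * series$pixel_area * dt
    retro <- retro + sum(pmax(-v, 0)) * series$pixel_area * dt
  }
  c(antegrade = ante, retrograde = retro)
}

#' Retrograde flow index and percentage retrograde flow
#'
#' The retrograde volume per beat is the frame-duration-weighted sum of
#' backward (negative-velocity) pixel flow.  The retrograde flow index
#' converts it to L/min and divides by body surface area; percentage
#' retrograde flow divides the retrograde by the antegrade volume per beat.
#' When the antegrade volume is zero the percentage is undefined and
#' returned as `NA` with a warning; the index is still returned.
#'
#' @param series a [velocity_series()].
#' @return named numeric vector `c(retrograde_flow_index =,
#'   retrograde_percent =)`, L/min/m^2 and percent.
#' @export
retrograde_metrics <- function(series) {
  bv <- beat_volumes(series)
  index <- bv[["retrograde"]] * (60 / series$rr_interval) / 1000 / series$bsa
  pct <- if (bv[["antegrade"]] > 0) {
    100 * bv[["retrograde"]] / bv[["antegrade"]]
  } else {
    warning("antegrade volume per beat is zero; retrograde percentage undefined")
    NA_real_
  }
  c(retrograde_flow_index = index, retrograde_percent = pct)
}

#' Pulmonary-artery area pulsatility
#'
#' Vessel areas from mask pixel counts per frame: systolic area is the
#' cycle maximum, diastolic the minimum, and the relative area change is
#' 100 x (max - min) / min.  Note the minimum-area denominator, unlike the
#' RV relative area change which divides by the diastolic (larger) area.
#'
#' @param series a [velocity_series()] with at least 2 frames.
#' @return named numeric vector `c(systolic_area =, diastolic_area =,
#'   pa_rac =)`, cm^2 and percent.
#' @export
pa_area_pulsatility <- function(series) {
  if (length(series$frames) < 2) {
    rhcmr_error("area pulsatility needs at least 2 frames",
                "rhcmr_invalid_series")
  }
  areas <- vapply(series$frames, function(f) sum(f$mask) * series$pixel_area,
                  numeric(1))
  c(systolic_area = max(areas), diastolic_area = min(areas),
    pa_rac = 100 * (max(areas) - min(areas)) / min(areas))
}

#' All phase-contrast indices for one series
#'
#' @param series a [velocity_series()].
#' @return a one-row data frame of class `flow_result` with columns
#'   `average_velocity` (cm/s), `retrograde_flow_index` (L/min/m^2),
#'   `retrograde_percent`, `systolic_area`, `diastolic_area` (cm^2) and
#'   `pa_rac` (percent).
#' @export
flow_metrics <- function(series) {
  rm <- retrograde_metrics(series)
  ap <- pa_area_pulsatility(series)
  out <- data.frame(
    average_velocity = average_velocity(series),
    retrograde_flow_index = unname(rm["retrograde_flow_index"]),
    retrograde_percent = unname(rm["retrograde_percent"]),
    systolic_area = unname(ap["systolic_area"]),
    diastolic_area = unname(ap["diastolic_area"]),
    pa_rac = unname(ap["pa_rac"]))
  class(out) <- c("flow_result", class(out))
  out
}

#' Read or write a velocity series as per-frame CSV grids
#'
#' Plain-text bundle: a directory containing `meta.json` (pixel_area_cm2,
#' rr_interval_s, bsa_m2, n_frames) and per frame `velNNN.csv` /
#' `maskNNN.csv` grids (velocities in cm/s, masks as 0/1).
#'
#' @param dir directory path.
#' @return `read_velocity_series()` returns a [velocity_series()];
#'   `write_velocity_series()` returns `dir` invisibly.
#' @export
read_velocity_series <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  frames <- lapply(seq_len(meta$n_frames), function(i) {
    v <- as.matrix(read.csv(file.path(dir, sprintf("vel%03d.csv", i)),
                            header = FALSE))
    m <- as.matrix(read.csv(file.path(dir, sprintf("mask%03d.csv", i)),
                            header = FALSE)) > 0
    dimnames(v) <- dimnames(m) <- NULL
    list(velocity = v, mask = m)
  })
  velocity_series(frames, meta$pixel_area_cm2, meta$rr_interval_s, meta$bsa_m2)
}

#' @rdname read_velocity_series
#' @param series a [velocity_series()].
#' @export
write_velocity_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(pixel_area_cm2 = series$pixel_area,
         rr_interval_s = series$rr_interval, bsa_m2 = series$bsa,
         n_frames = length(series$frames)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(series$frames)) {
    write.table(series$frames[[i]]$velocity,
                file.path(dir, sprintf("vel%03d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
    write.table(series$frames[[i]]$mask * 1L,
                file.path(dir, sprintf("mask%03d.csv", i)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
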