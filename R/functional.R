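# Four-chamber functional indices: longitudinal (TAPSE, f-TAAD), transverse
# (SFD excursion, f-SFD), RV relative area change, and the LV eccentricity
# index from mid-ventricular short-axis diameters.

#' Four-chamber landmark frame
#'
#' Manually placed landmarks on a 4-chamber cine frame: the tricuspid
#' annulus, the RV apex, and the septal and free-wall points whose distance
#' is the septum-free-wall perpendicular distance (SFD) at mid-ventricle
#' (taken at 50% of the apex-annulus axis).  Coordinates in mm; `rv_area`
#' is the planimetered RV area on the same frame in mm^2.
#'
#' @param phase `"ED"` or `"ES"`.
#' @param tricuspid_annulus,rv_apex,septal_mid,freewall_mid length-2 numeric
#'   points (mm).
#' @param rv_area RV endocardial area on the frame, mm^2 (> 0).
#' @return an object of class `four_chamber_frame`.
#' @export
four_chamber_frame <- function(phase, tricuspid_annulus, rv_apex,
                               septal_mid, freewall_mid, rv_area) {
  phase <- match.arg(phase, c("ED", "ES"))
  pts <- list(tricuspid_annulus = tricuspid_annulus, rv_apex = rv_apex,
              septal_mid = septal_mid, freewall_mid = freewall_mid)
  for (nm in names(pts)) {
    if (!is_point(pts[[nm]])) {
      rhcmr_error(sprintf("%s must be a finite 2D point in mm", nm),
                  "rhcmr_invalid_landmarks")
    }
  }
  if (!is.numeric(rv_area) || length(rv_area) != 1 || rv_area <= 0) {
    rhcmr_error("rv_area must be a positive area in mm^2",
                "rhcmr_invalid_landmarks")
  }
  if (isTRUE(all(tricuspid_annulus == rv_apex))) {
    rhcmr_error("tricuspid annulus and RV apex coincide",
                "rhcmr_invalid_landmarks")
  }
  structure(c(lapply(pts, as.numeric), list(phase = phase,
                                            rv_area = rv_area)),
            class = "four_chamber_frame")
}

dist_mm <- function(a, b) sqrt(sum((a - b)^2))

taad_cm <- function(frame) {
  d <- dist_mm(frame$tricuspid_annulus, frame$rv_apex)
  if (d == 0) {
    rhcmr_error("degenerate frame: annulus-apex distance is zero",
                "rhcmr_invalid_landmarks")
  }
  d / MM_PER_CM
}

sfd_cm <- function(frame) {
  dist_mm(frame$septal_mid, frame$freewall_mid) / MM_PER_CM
}

#' Tricuspid annular plane systolic excursion (TAPSE)
#'
#' Change of the tricuspid annulus-apex distance between end-diastole and
#' end-systole, in cm.  Negative values (paradoxical motion) are returned
#' as-is, not clamped.
#'
#' @param ed,es [four_chamber_frame()] objects at end-diastole and
#'   end-systole.
#' @return excursion in cm.
#' @export
tapse <- function(ed, es) {
  taad_cm(ed) - taad_cm(es)
}

#' Fractional tricuspid annulus-apex distance change (f-TAAD)
#'
#' TAPSE divided by the end-diastolic annulus-apex distance, as a
#' percentage; the scale-free form of longitudinal RV function.
#'
#' @inheritParams tapse
#' @return percent.
#' @export
fractional_taad <- function(ed, es) {
  100 * tapse(ed, es) / taad_cm(ed)
}

#' Transverse RV function: septum-free-wall distance excursion
#'
#' SFD excursion is the change of the septum-free-wall perpendicular
#' distance at mid-ventricle between end-diastole and end-systole (cm);
#' fractional SFD expresses it as a percentage of the end-diastolic SFD.
#'
#' @inheritParams tapse
#' @return named numeric vector `c(sfd =, f_sfd =)`, cm and percent.
#' @export
septum_freewall_excursion <- function(ed, es) {
  s_ed <- sfd_cm(ed)
  if (s_ed <= 0) {
    rhcmr_error("end-diastolic septum-free-wall distance must be positive",
                "rhcmr_invalid_landmarks")
  }
  s <- s_ed - sfd_cm(es)
  c(sfd = s, f_sfd = 100 * s / s_ed)
}

#' RV relative area change on the 4-chamber view
#'
#' RVRAC = 100 x (diastolic area - systolic area) / diastolic area.  Note
#' the end-diastolic denominator, unlike the pulmonary-artery relative area
#' change (see [pa_area_pulsatility()]) which divides by the minimum area.
#'
#' @inheritParams tapse
#' @return percent.
#' @export
rv_relative_area_change <- function(ed, es) {
  100 * (ed$rv_area - es$rv_area) / ed$rv_area
}

#' Left-ventricular eccentricity index
#'
#' EI = D2 / D1 from two perpendicular LV minor-axis diameters on the
#' mid-chamber short-axis image, where D2 is parallel and D1 perpendicular
#' to the inter-ventricular septum.  Applied to the end-systolic frame this
#' is sEI, to the end-diastolic frame dEI; values above 1.2 indicate septal
#' flattening.
#'
#' @param d1 diameter perpendicular to the septum, mm or cm (> 0).
#' @param d2 diameter parallel to the septum, same unit as `d1`.
#' @return dimensionless ratio.
#' @export
#' @examples
#' eccentricity_index(d1 = 50, d2 = 60)  # 1.2
eccentricity_index <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(d1 <= 0) || any(!is.finite(d2)) ||
      any(d2 <= 0)) {
    rhcmr_error("eccentricity diameters must be positive",
                "rhcmr_invalid_diameters")
  }
  d2 / d1
}

#' All functional metrics from a landmark pair and mid-slice diameters
#'
#' Convenience wrapper computing TAPSE, f-TAAD, SFD excursion, f-SFD,
#' RVRAC, and (when diameters are supplied) sEI and dEI.
#'
#' @inheritParams tapse
#' @param diam_ed,diam_es optional named vectors `c(d1 =, d2 =)` of
#'   mid-chamber LV diameters at ED and ES.
#' @return a one-row data frame of class `functional_metrics`.
#' @export
functional_metrics <- function(ed, es, diam_ed = NULL, diam_es = NULL) {
  sf <- septum_freewall_excursion(ed, es)
  out <- data.frame(
    tapse = tapse(ed, es),
    f_taad = fractional_taad(ed, es),
    sfd = unname(sf["sfd"]),
    f_sfd = unname(sf["f_sfd"]),
    rvrac = rv_relative_area_change(ed, es),
    sei = if (is.null(diam_es)) NA_real_ else
      eccentricity_index(diam_es[["d1"]], diam_es[["d2"]]),
    dei = if (is.null(diam_ed)) NA_real_ else
      eccentricity_index(diam_ed[["d1"]], diam_ed[["d2"]]))
  class(out) <- c("functional_metrics", class(out))
  out
}
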