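# Short-axis volumetry: Simpson slice summation, ED/ES phase selection,
# cavity volumes, myocardial mass and the ventricular mass index.

#' Cavity or wall volume by slice summation
#'
#' Sums polygon area times inter-slice distance over all slices carrying a
#' contour of the requested structure at the requested phase (Simpson's
#' method on a contiguous short-axis stack).  Slices without a contour
#' contribute zero volume; no apical or basal extrapolation is performed.
#'
#' @param stack a [contour_stack()].
#' @param structure one of `"RV_ENDO"`, `"RV_EPI"`, `"LV_ENDO"`, `"LV_EPI"`.
#' @param phase integer cine phase index.
#' @return volume in mL.
#' @export
stack_volume <- function(stack, structure, phase) {
  structure <- match.arg(structure, CONTOUR_STRUCTURES)
  sel <- Filter(function(k) k$structure == structure && k$phase == phase,
                stack$contours)
  if (length(sel) == 0) {
    rhcmr_error(
      sprintf("no %s contours at phase %d", structure, as.integer(phase)),
      "rhcmr_missing_structure")
  }
  areas <- vapply(sel, function(k) polygon_area(k$vertices), numeric(1))
  sum(areas) * stack$slice_spacing / MM3_PER_ML
}

#' Select end-diastolic and end-systolic phases
#'
#' End-diastole is the first cine phase of the R-wave-triggered acquisition
#' (phase 0).  End-systole is the phase with the smallest summed endocardial
#' cavity volume across the stack; ties are broken in favour of the earliest
#' phase.  A global (summed) minimum is used rather than per-slice minima,
#' which would compose a non-physical phase.
#'
#' @param stack a [contour_stack()].
#' @param structure ventricle, `"RV"` or `"LV"`; the endocardial contours of
#'   that side are used.
#' @return named integer vector `c(ed_phase =, es_phase =)`.
#' @export
select_ed_es_phases <- function(stack, structure = c("RV", "LV")) {
  structure <- match.arg(structure)
  endo <- paste0(structure, "_ENDO")
  phases <- sort(unique(vapply(
    Filter(function(k) k$structure == endo, stack$contours),
    `[[`, integer(1), "phase")))
  if (length(phases) < 2) {
    rhcmr_error(
      sprintf("need endocardial contours in at least 2 phases to select ES (found %d)",
              length(phases)),
      "rhcmr_insufficient_phases")
  }
  vols <- vapply(phases, function(p) stack_volume(stack, endo, p), numeric(1))
  c(ed_phase = 0L, es_phase = phases[which.min(vols)])
}

#' Full ventricular volumetrics for one patient
#'
#' Computes RV end-diastolic and end-systolic cavity volumes, stroke volume
#' and ejection fraction from the RV endocardial contours, and ventricular
#' masses from the end-diastolic epi/endocardial pairs: per-slice myocardial
#' volume is (epicardial area - endocardial area) x inter-slice distance,
#' and mass is myocardial volume x 1.05 g/cm^3.  The inter-ventricular
#' septum belongs to the LV wall, so the RV epicardial contour covers the
#' free wall only.  Volumes and stroke volume are additionally indexed to
#' body surface area, and the ventricular mass index VMI = RV mass / LV mass
#' is reported.
#'
#' @param stack a [contour_stack()].
#' @param bsa body surface area in m^2 (> 0); see [bsa_from_height_weight()].
#' @param es_mode `"per_structure"` selects the LV end-systolic phase from
#'   the LV volume curve independently of the RV; `"shared"` applies the RV
#'   end-systolic phase to both ventricles.  Masses are end-diastolic either
#'   way, so only cavity metrics of the LV (not reported here) would differ.
#' @return an object of class `volumetrics_result`: list with elements
#'   `rv_edv`, `rv_esv`, `rv_sv` (mL), `rv_ef` (percent), `rv_mass`,
#'   `lv_mass` (g), `rv_edvi`, `rv_svi` (mL/m^2), `rv_mass_index` (g/m^2),
#'   `vmi` (ratio), `ed_phase`, `es_phase`.
#' @export
#' @examples
#' ph <- make_ventricle_phantom(ventricle_phantom_spec(shape = "SHELL"))
#' ventricular_volumetrics(ph$stack, bsa = 1.9)
ventricular_volumetrics <- function(stack, bsa,
                                    es_mode = c("per_structure", "shared")) {
  es_mode <- match.arg(es_mode)
  if (!is.numeric(bsa) || length(bsa) != 1 || !is.finite(bsa) || bsa <= 0) {
    rhcmr_error("bsa must be a positive area in m^2", "rhcmr_invalid_bsa")
  }
  ph <- select_ed_es_phases(stack, "RV")
  ed <- ph[["ed_phase"]]; es <- ph[["es_phase"]]

  rv_edv <- stack_volume(stack, "RV_ENDO", ed)
  rv_esv <- stack_volume(stack, "RV_ENDO", es)
  rv_sv <- rv_edv - rv_esv
  rv_ef <- if (rv_edv > 0) 100 * rv_sv / rv_edv else NA_real_

  rv_mass <- ventricular_mass(stack, "RV", ed)
  lv_mass <- ventricular_mass(stack, "LV", ed)
  vmi <- if (!is.na(lv_mass) && lv_mass > 0) rv_mass / lv_mass else NA_real_

  structure(list(
    rv_edv = rv_edv, rv_esv = rv_esv, rv_sv = rv_sv, rv_ef = rv_ef,
    rv_mass = rv_mass, lv_mass = lv_mass,
    rv_edvi = rv_edv / bsa, rv_svi = rv_sv / bsa,
    rv_mass_index = rv_mass / bsa, vmi = vmi,
    ed_phase = ed, es_phase = es, bsa = bsa, es_mode = es_mode),
    class = "volumetrics_result")
}

# mass (g) of one ventricle's wall at one phase; NA when that side has no
# epicardial contours (mass simply not measured for the patient).
ventricular_mass <- function(stack, side = c("RV", "LV"), phase) {
  side <- match.arg(side)
  epi <- paste0(side, "_EPI"); endo <- paste0(side, "_ENDO")
  has_epi <- any(vapply(stack$contours, function(k) {
    k$structure == epi && k$phase == phase
  }, logical(1)))
  if (!has_epi) return(NA_real_)
  wall_ml <- stack_volume(stack, epi, phase) - stack_volume(stack, endo, phase)
  wall_ml * MYOCARDIAL_DENSITY_G_PER_CM3  # mL == cm^3
}

#' @export
print.volumetrics_result <- function(x, ...) {
  cat("<volumetrics_result>\n")
  cat(sprintf("  RV EDV %.1f mL  ESV %.1f mL  SV %.1f mL  EF %.1f%%  (ED phase %d, ES phase %d)\n",
              x$rv_edv, x$rv_esv, x$rv_sv, x$rv_ef, x$ed_phase, x$es_phase))
  cat(sprintf("  RV mass %.1f g  LV mass %.1f g  VMI %.2f\n",
              x$rv_mass, x$lv_mass, x$vmi))
  cat(sprintf("  indexed (BSA %.2f m^2): RVEDVI %.1f  RVSVI %.1f mL/m^2, RV mass index %.1f g/m^2\n",
              x$bsa, x$rv_edvi, x$rv_svi, x$rv_mass_index))
  invisible(x)
}

#' @export
as.data.frame.volumetrics_result <- function(x, ...) {
  keep <- c("rv_edv", "rv_esv", "rv_sv", "rv_ef", "rv_mass", "lv_mass",
            "rv_edvi", "rv_svi", "rv_mass_index", "vmi", "ed_phase",
            "es_phase")
  as.data.frame(x[keep])
}

#' Body surface area (Du Bois)
#'
#' BSA = 0.007184 * height^0.725 * weight^0.425, height in cm and weight in
#' kg.  Cohort tables may carry a measured BSA directly, in which case this
#' helper is bypassed.
#'
#' @param height_cm height in cm (> 0).
#' @param weight_kg weight in kg (> 0).
#' @return body surface area in m^2.
#' @export
#' @examples
#' bsa_from_height_weight(180, 75)  # ~1.94
bsa_from_height_weight <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    rhcmr_error("height and weight must be positive",
                "rhcmr_invalid_anthropometry")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}
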