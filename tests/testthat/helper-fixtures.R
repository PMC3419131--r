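# Shared fixture builders: tiny contour stacks with known areas, built in
# code at test time.

square_vertices <- function(side, centre = c(0, 0)) {
  half <- side / 2
  cbind(centre[1] + c(-half, half, half, -half),
        centre[2] + c(-half, -half, half, half))
}

# a stack whose RV endocardial volume by phase (mL) is given exactly, using
# one square contour per phase on a single slice
stack_with_phase_volumes <- function(volumes_ml, spacing = 10) {
  contours <- lapply(seq_along(volumes_ml) - 1, function(p) {
    area_mm2 <- volumes_ml[p + 1] * 1000 / spacing
    slice_contour("RV_ENDO", 0, p, square_vertices(sqrt(area_mm2)))
  })
  contour_stack("fix", spacing, contours)
}

# concentric square shell stack at ED/ES for mass work: endo/epi areas in
# mm^2 per slice, constant across slices
square_shell_stack <- function(n_slices = 10, spacing = 10,
                               rv_endo_area = 400, rv_wall_area = 300,
                               lv_endo_area = 400, lv_wall_area = 600,
                               es_scale = 0.5) {
  contours <- list()
  for (i in seq_len(n_slices) - 1) {
    contours <- c(contours, list(
      slice_contour("RV_ENDO", i, 0, square_vertices(sqrt(rv_endo_area))),
      slice_contour("RV_EPI", i, 0,
                    square_vertices(sqrt(rv_endo_area + rv_wall_area))),
      slice_contour("LV_ENDO", i, 0,
                    square_vertices(sqrt(lv_endo_area), centre = c(100, 0))),
      slice_contour("LV_EPI", i, 0,
                    square_vertices(sqrt(lv_endo_area + lv_wall_area),
                                    centre = c(100, 0))),
      slice_contour("RV_ENDO", i, 1,
                    square_vertices(sqrt(rv_endo_area * es_scale)))))
  }
  contour_stack("shellfix", spacing, contours)
}

# independent Fisher-test oracle: enumerate all tables with the observed
# margins via binomial-coefficient products
fisher_enum <- function(tp, fp, fn, tn) {
  m <- tp + fn; n <- fp + tn; k <- tp + fp
  if (m == 0 || n == 0 || k == 0 || fn + tn == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- choose(m, tp) * choose(n, fp) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

rigid_transform_stack <- function(stack, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  contours <- lapply(stack$contours, function(k) {
    v <- t(R %*% t(k$vertices)) + rep(shift, each = nrow(k$vertices))
    slice_contour(k$structure, k$slice, k$phase, v)
  })
  contour_stack(stack$patient_id, stack$slice_spacing, contours,
                n_slices = stack$n_slices, n_phases = stack$n_phases)
}
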