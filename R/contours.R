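# Contour containers: segmented polygons per slice/phase/structure, the
# substrate for all short-axis volumetry and mass estimation.

CONTOUR_STRUCTURES <- c("RV_ENDO", "RV_EPI", "LV_ENDO", "LV_EPI")

#' Create a single slice contour
#'
#' One manually traced polygon on one short-axis slice at one cine phase.
#' Vertices are ordered boundary points in mm; the polygon must be simple
#' (non-self-intersecting) with positive area.  The inter-ventricular septum
#' is counted with the left ventricle, so an `RV_EPI` contour traces the RV
#' free wall only.
#'
#' @param structure one of `"RV_ENDO"`, `"RV_EPI"`, `"LV_ENDO"`, `"LV_EPI"`.
#' @param slice integer slice index, 0-based, base to apex.
#' @param phase integer cine phase index, 0-based; phase 0 is end-diastole
#'   (first phase of the R-wave-triggered acquisition).
#' @param vertices numeric matrix (n x 2) or list of length-2 vectors, mm.
#' @return an object of class `slice_contour`.
#' @export
#' @examples
#' sc <- slice_contour("RV_ENDO", 0, 0, cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' polygon_area(sc$vertices)
slice_contour <- function(structure, slice, phase, vertices) {
  structure <- match.arg(structure, CONTOUR_STRUCTURES)
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2) {
    rhcmr_error("a contour needs at least 3 two-dimensional vertices",
                "rhcmr_invalid_contour")
  }
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices))) {
    rhcmr_error("contour vertices must be finite", "rhcmr_invalid_contour")
  }
  if (!is_simple_polygon(vertices)) {
    rhcmr_error("contour polygon is self-intersecting",
                "rhcmr_invalid_contour")
  }
  if (polygon_area(vertices) <= 0) {
    rhcmr_error("contour polygon has zero area", "rhcmr_invalid_contour")
  }
  structure(list(structure = structure, slice = as.integer(slice),
                 phase = as.integer(phase), vertices = vertices),
            class = "slice_contour")
}

#' Absolute polygon area by the shoelace formula
#'
#' Orientation-independent: clockwise and counter-clockwise vertex orderings
#' give the same area.
#'
#' @param vertices numeric matrix (n x 2) of ordered polygon vertices, mm.
#' @return area in mm^2.
#' @export
#' @examples
#' polygon_area(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))  # 100
polygon_area <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (is.null(n) || n < 3 || ncol(vertices) != 2) {
    rhcmr_error("polygon area needs at least 3 two-dimensional vertices",
                "rhcmr_invalid_contour")
  }
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(n, seq_len(n - 1))  # previous vertex, wrapping
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Simple-polygon check by pairwise proper segment intersection.  Adjacent
# edges (sharing a vertex) are exempt.  O(n^2) but contours are small.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  segs <- cbind(v, v[nxt, , drop = FALSE])  # x1 y1 x2 y2 per edge
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # skip edges sharing an endpoint (consecutive, incl. wrap-around)
      if (j == i + 1 || (i == 1 && j == n)) next
      a <- segs[i, ]; b <- segs[j, ]
      d1 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d2 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      d3 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d4 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Assemble a contour stack for one patient
#'
#' Collects all segmented polygons for one patient across slices, phases and
#' structures.  `slice_spacing` is the effective inter-slice distance
#' (slice thickness plus gap); the default 10 mm corresponds to 8 mm slices
#' with a 2 mm gap.
#'
#' @param patient_id character scalar.
#' @param slice_spacing inter-slice distance in mm (> 0).
#' @param contours list of [slice_contour()] objects.
#' @param n_slices,n_phases optional integers; inferred from `contours` when
#'   omitted.
#' @param landmarks optional named list of four-chamber landmark frames (see
#'   [four_chamber_frame()]) carried alongside the short-axis contours.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(patient_id, slice_spacing, contours,
                          n_slices = NULL, n_phases = NULL,
                          landmarks = NULL) {
  if (!is.numeric(slice_spacing) || length(slice_spacing) != 1 ||
      slice_spacing <= 0) {
    rhcmr_error("slice_spacing must be a positive length in mm",
                "rhcmr_invalid_stack")
  }
  if (!all(vapply(contours, inherits, logical(1), "slice_contour"))) {
    rhcmr_error("contours must be a list of slice_contour objects",
                "rhcmr_invalid_stack")
  }
  key <- vapply(contours, function(k) {
    paste(k$structure, k$slice, k$phase, sep = "/")
  }, character(1))
  if (anyDuplicated(key)) {
    rhcmr_error(
      sprintf("duplicate contour for (structure, slice, phase): %s",
              key[duplicated(key)][1]),
      "rhcmr_invalid_stack")
  }
  slices <- vapply(contours, `[[`, integer(1), "slice")
  phases <- vapply(contours, `[[`, integer(1), "phase")
  n_slices <- as.integer(n_slices %||% (max(slices) + 1L))
  n_phases <- as.integer(n_phases %||% (max(phases) + 1L))
  stk <- structure(list(patient_id = as.character(patient_id),
                        slice_spacing = slice_spacing,
                        n_slices = n_slices, n_phases = n_phases,
                        contours = contours, landmarks = landmarks),
                   class = "contour_stack")
  check_epi_encloses_endo(stk)
  stk
}

# Epicardial area must be >= the matching endocardial area on every
# slice/phase where both are present.
check_epi_encloses_endo <- function(stack) {
  for (side in c("RV", "LV")) {
    epi <- contour_lookup(stack, paste0(side, "_EPI"))
    endo <- contour_lookup(stack, paste0(side, "_ENDO"))
    shared <- intersect(names(epi), names(endo))
    for (k in shared) {
      if (polygon_area(epi[[k]]$vertices) <
          polygon_area(endo[[k]]$vertices)) {
        rhcmr_error(
          sprintf("%s epicardial contour at %s has smaller area than its endocardial contour",
                  side, k),
          "rhcmr_inconsistent_contour")
      }
    }
  }
  invisible(stack)
}

# named list "slice/phase" -> contour, for one structure
contour_lookup <- function(stack, structure) {
  sel <- Filter(function(k) k$structure == structure, stack$contours)
  setNames(sel, vapply(sel, function(k) paste(k$slice, k$phase, sep = "/"),
                       character(1)))
}

#' @export
print.contour_stack <- function(x, ...) {
  tab <- table(vapply(x$contours, `[[`, character(1), "structure"))
  cat(sprintf("<contour_stack> patient %s: %d slices x %d phases, spacing %g mm\n",
              x$patient_id, x$n_slices, x$n_phases, x$slice_spacing))
  cat("  contours:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(x$landmarks)) cat("  landmarks: present\n")
  invisible(x)
}

#' Read or write the per-patient contour JSON format
#'
#' One JSON file per patient:
#' `{patient_id, slice_spacing_mm, n_slices, n_phases,`
#' `contours: [{structure, slice, phase, vertices: [[x,y],...]}],`
#' `landmarks: {...}}` with coordinates in mm.
#'
#' @param path file path.
#' @return `read_contour_json()` returns a [contour_stack()];
#'   `write_contour_json()` returns `path` invisibly.
#' @export
read_contour_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  contours <- lapply(raw$contours, function(k) {
    v <- k$vertices
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    slice_contour(k$structure, k$slice, k$phase, v)
  })
  landmarks <- if (!is.null(raw$landmarks)) {
    lapply(raw$landmarks, function(fr) {
      four_chamber_frame(
        phase = fr$phase,
        tricuspid_annulus = unlist(fr$tricuspid_annulus),
        rv_apex = unlist(fr$rv_apex),
        septal_mid = unlist(fr$septal_mid),
        freewall_mid = unlist(fr$freewall_mid),
        rv_area = fr$rv_area)
    })
  }
  contour_stack(raw$patient_id, raw$slice_spacing_mm, contours,
                n_slices = raw$n_slices, n_phases = raw$n_phases,
                landmarks = landmarks)
}

#' @rdname read_contour_json
#' @param stack a [contour_stack()].
#' @export
write_contour_json <- function(stack, path) {
  out <- list(
    patient_id = stack$patient_id,
    slice_spacing_mm = stack$slice_spacing,
    n_slices = stack$n_slices,
    n_phases = stack$n_phases,
    contours = lapply(stack$contours, function(k) {
      list(structure = k$structure, slice = k$slice, phase = k$phase,
           vertices = unname(k$vertices))
    }))
  if (!is.null(stack$landmarks)) {
    out$landmarks <- lapply(stack$landmarks, function(fr) {
      list(phase = fr$phase,
           tricuspid_annulus = unname(fr$tricuspid_annulus),
           rv_apex = unname(fr$rv_apex),
           septal_mid = unname(fr$septal_mid),
           freewall_mid = unname(fr$freewall_mid),
           rv_area = fr$rv_area)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
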