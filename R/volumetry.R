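#' Planimetric area of a contour polygon
#'
#' Area of a simple (non-self-intersecting) planar polygon by the shoelace
#' formula, independent of vertex orientation. Vertices are in mm, in tracing
#' order, without repeating the first vertex.
#'
#' @param vertices Two-column numeric matrix (or data.frame) of x, y
#'   coordinates in mm; at least 3 vertices.
#' @return Area in mm^2 (non-negative).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop("vertices must be an n x 2 numeric matrix")
  }
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Build a short-axis contour stack
#'
#' A contour stack holds one cardiac phase's short-axis segmentation: per
#' slice, the endocardial (blood-pool) polygon and, optionally, the epicardial
#' polygon, together with the acquisition geometry. Endocardial contours are
#' blood-pool boundaries: papillary muscles are inside the contour (part of
#' the pool) by convention.
#'
#' @param slices List of slices, each a list with `index` (integer, base to
#'   apex), `endo` (n x 2 matrix, mm) and optionally `epi`.
#' @param slice_thickness Slice thickness in mm (> 0).
#' @param gap Inter-slice gap in mm (>= 0). Defaults follow the cine protocol
#'   (6 mm slices, 4 mm gap).
#' @param phase `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(slices, slice_thickness = 6, gap = 4,
                          phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  if (!is.list(slices) || length(slices) < 1L) {
    stop("a contour stack needs at least one slice")
  }
  if (!is.numeric(slice_thickness) || slice_thickness <= 0) {
    stop("slice_thickness must be > 0")
  }
  if (!is.numeric(gap) || gap < 0) stop("gap must be >= 0")
  slices <- lapply(slices, function(s) {
    if (is.null(s$endo)) stop("every slice must carry an endocardial contour")
    s$endo <- as.matrix(s$endo)
    if (!is.null(s$epi)) {
      s$epi <- as.matrix(s$epi)
      if (polygon_area(s$epi) < polygon_area(s$endo) - 1e-9) {
        stop("epicardial area smaller than endocardial area on slice ",
             s$index)
      }
    }
    s
  })
  structure(
    list(slices = slices, slice_thickness = slice_thickness, gap = gap,
         phase = phase),
    class = "contour_stack"
  )
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf(
    "Short-axis contour stack (%s): %d slices, %.1f mm slices + %.1f mm gap\n",
    x$phase, length(x$slices), x$slice_thickness, x$gap))
  cat(sprintf("  epicardial contours: %s\n",
              if (all(vapply(x$slices, function(s) !is.null(s$epi),
                             logical(1)))) "all slices" else "absent/partial"))
  invisible(x)
}

#' Disc-summation (Simpson rule) ventricular volume
#'
#' Sums, base to apex, each slice's contour area times the effective slab
#' thickness (slice thickness plus inter-slice gap — each contour stands for
#' its slab through the half-gaps on either side), and converts mm^3 to ml.
#'
#' @param stack A [contour_stack()].
#' @param surface `"endo"` for the cavity (blood-pool) volume or `"epi"` for
#'   the volume enclosed by the epicardium.
#' @return Volume in ml.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)) * sqrt(10)
#' st <- contour_stack(list(list(index = 1, endo = sq)), 6, 4, "ED")
#' simpson_volume(st)  # 1000 mm^2 x 10 mm = 10 ml
#' @export
simpson_volume <- function(stack, surface = c("endo", "epi")) {
  stopifnot(inherits(stack, "contour_stack"))
  surface <- match.arg(surface)
  polys <- lapply(stack$slices, `[[`, surface)
  if (any(vapply(polys, is.null, logical(1)))) {
    stop("surface '", surface, "' missing on some slices")
  }
  areas <- vapply(polys, polygon_area, numeric(1))
  span <- stack$slice_thickness + stack$gap
  sum(areas * span) / 1000
}

#' Left-ventricular mass from an end-diastolic stack
#'
#' Myocardial volume is the epicardial minus the endocardial disc-summation
#' volume at end-diastole; mass applies the standard myocardial density.
#'
#' @param ed_stack End-diastolic [contour_stack()] with both surfaces traced.
#' @param density Myocardial density in g/ml (default 1.05).
#' @return Mass in g.
#' @export
lv_mass <- function(ed_stack, density = 1.05) {
  epi <- simpson_volume(ed_stack, "epi")
  endo <- simpson_volume(ed_stack, "endo")
  if (epi < endo - 1e-9) {
    stop("epicardial volume smaller than endocardial volume")
  }
  max(epi - endo, 0) * density
}

#' Body surface area by the DuBois formula
#'
#' \deqn{BSA = 0.007184 \times weight^{0.425} \times height^{0.725}}
#' with weight in kg and height in cm; used to index cardiac volumes and mass.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return BSA in m^2 (vectorised).
#' @examples
#' dubois_bsa(180, 70)  # 1.886
#' @export
dubois_bsa <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive")
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Left-ventricular global function index
#'
#' LVGFI relates stroke volume to the "global" ventricular volume — the mean
#' cavity volume across the cycle plus the myocardial volume:
#' \deqn{LVGFI = \frac{SV}{(EDV + ESV)/2 + LVM/\rho}}
#' with myocardial density \eqn{\rho} (1.05 g/ml). Reported as a unitless
#' fraction. The inputs may be raw volumes or BSA-indexed values, as long as
#' they share one scale — the index is scale-invariant.
#'
#' @param lvsv,lvedv,lvesv Volumes (ml or ml/m^2).
#' @param lvm Mass (g or g/m^2), on the same indexing as the volumes.
#' @param density Myocardial density, g/ml.
#' @return LVGFI as a fraction.
#' @examples
#' lv_gfi(45.1, 68.7, 24.9, 50.9)  # 0.47
#' @export
lv_gfi <- function(lvsv, lvedv, lvesv, lvm, density = 1.05) {
  global_vol <- (lvedv + lvesv) / 2 + lvm / density
  lvsv / global_vol
}

#' Derive the full left-ventricular metric set from contour stacks
#'
#' Runs disc-summation volumetry on the end-diastolic and end-systolic stacks
#' and derives mass, stroke volume, ejection fraction, mass-to-volume ratio
#' and global function index, each also indexed to DuBois body surface area.
#'
#' The mass-to-volume ratio is reported as LVM/LVEDV in g/ml by default, the
#' direction matching its printed unit as a concentricity index;
#' `lvmvr = "volume_over_mass"` emits the reciprocal LVEDV/LVM instead.
#'
#' @param ed_stack,es_stack End-diastolic and end-systolic [contour_stack()]s;
#'   `ed_stack` must carry epicardial contours.
#' @param height_cm,weight_kg Body habitus for BSA indexing.
#' @param lvmvr Direction of the mass-volume ratio (see Details).
#' @param density Myocardial density, g/ml.
#' @return An object of class `lv_metrics`: a list with `lvedv`, `lvesv`,
#'   `lvsv` (ml), `lvef` (percent), `lvm` (g), `lvmvr`, `lvgfi`, `bsa` (m^2)
#'   and BSA-indexed `lvedv_i`, `lvesv_i`, `lvsv_i` (ml/m^2), `lvm_i` (g/m^2).
#' @export
derive_metrics <- function(ed_stack, es_stack, height_cm, weight_kg,
                           lvmvr = c("mass_over_volume", "volume_over_mass"),
                           density = 1.05) {
  lvmvr <- match.arg(lvmvr)
  stopifnot(inherits(ed_stack, "contour_stack"),
            inherits(es_stack, "contour_stack"))
  edv <- simpson_volume(ed_stack, "endo")
  esv <- simpson_volume(es_stack, "endo")
  if (esv > edv + 1e-9) {
    stop("end-systolic volume exceeds end-diastolic volume")
  }
  esv <- min(esv, edv)
  sv <- edv - esv
  if (edv <= 0) {
    warning("ejection fraction undefined: zero end-diastolic volume",
            call. = FALSE)
    ef <- NA_real_
  } else {
    ef <- 100 * sv / edv
  }
  lvm <- lv_mass(ed_stack, density = density)
  bsa <- dubois_bsa(height_cm, weight_kg)
  mvr <- if (edv > 0 && lvm > 0) {
    if (lvmvr == "mass_over_volume") lvm / edv else edv / lvm
  } else NA_real_
  gfi <- if (edv > 0) lv_gfi(sv, edv, esv, lvm, density) else NA_real_
  structure(
    list(
      lvedv = edv, lvesv = esv, lvsv = sv, lvef = ef, lvm = lvm,
      lvmvr = mvr, lvmvr_direction = lvmvr, lvgfi = gfi, bsa = bsa,
      lvedv_i = edv / bsa, lvesv_i = esv / bsa, lvsv_i = sv / bsa,
      lvm_i = lvm / bsa
    ),
    class = "lv_metrics"
  )
}

#' @export
print.lv_metrics <- function(x, ...) {
  cat("Left-ventricular metrics\n")
  cat(sprintf("  EDV %.1f ml (%.1f ml/m2)   ESV %.1f ml (%.1f ml/m2)\n",
              x$lvedv, x$lvedv_i, x$lvesv, x$lvesv_i))
  cat(sprintf("  SV  %.1f ml (%.1f ml/m2)   EF  %.1f %%\n",
              x$lvsv, x$lvsv_i, x$lvef))
  cat(sprintf("  LVM %.1f g (%.1f g/m2)    MVR %.2f (%s)   GFI %.2f\n",
              x$lvm, x$lvm_i, x$lvmvr,
              if (x$lvmvr_direction == "mass_over_volume") "g/ml" else "ml/g",
              x$lvgfi))
  cat(sprintf("  BSA %.3f m2\n", x$bsa))
  invisible(x)
}

#' Read and write contour stacks as JSON
#'
#' The interchange format is a JSON array of stacks:
#' `{participant_id, phase, slice_thickness_mm, gap_mm,
#'   slices: [{index, endo: [[x,y],...], epi: [[x,y],...]}]}`
#' with coordinates in mm in each slice plane.
#'
#' @param stacks Named list: per participant, a list with elements `ED` and/or
#'   `ES`, each a [contour_stack()].
#' @param path JSON file path.
#' @return `read_contour_stacks()` returns such a named list;
#'   `write_contour_stacks()` returns `path` invisibly.
#' @export
write_contour_stacks <- function(stacks, path) {
  recs <- list()
  for (pid in names(stacks)) {
    for (ph in names(stacks[[pid]])) {
      st <- stacks[[pid]][[ph]]
      recs[[length(recs) + 1L]] <- list(
        participant_id = pid, phase = st$phase,
        slice_thickness_mm = st$slice_thickness, gap_mm = st$gap,
        slices = lapply(st$slices, function(s) {
          mat_to_rows <- function(m) {
            lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
          }
          out <- list(index = s$index, endo = mat_to_rows(s$endo))
          if (!is.null(s$epi)) out$epi <- mat_to_rows(s$epi)
          out
        })
      )
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_stacks
#' @export
read_contour_stacks <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (r in recs) {
    to_mat <- function(p) {
      do.call(rbind, lapply(p, function(v) c(as.numeric(v[[1]]),
                                             as.numeric(v[[2]]))))
    }
    slices <- lapply(r$slices, function(s) {
      sl <- list(index = as.integer(s$index), endo = to_mat(s$endo))
      if (!is.null(s$epi)) sl$epi <- to_mat(s$epi)
      sl
    })
    st <- contour_stack(slices, r$slice_thickness_mm, r$gap_mm,
                        phase = r$phase)
    out[[r$participant_id]][[r$phase]] <- st
  }
  out
}
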