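# Pore-radius profiling: at each axial position the radius of the
# largest sphere, centred in that z-plane, that touches no atom's van
# der Waals surface -- the inscribed-sphere construction popularised by
# HOLE, here with a deterministic grid + local-polish search in place of
# Monte-Carlo annealing so results are exactly reproducible.

# Bondi van der Waals radii (Angstrom) by element.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, K = 2.75,
            "NA" = 2.27, MG = 1.73, ZN = 1.39, CA = 2.31)

#' Van der Waals radii for a structure model
#'
#' @param model A [structure_model()].
#' @param table Named vector of radii by element symbol (default:
#'   Bondi set).
#' @param default Radius used for unknown elements.
#' @return Numeric vector, one radius per atom (Angstrom).
#' @export
vdw_radii <- function(model, table = .BONDI, default = 1.70) {
  el <- toupper(model$elesy)
  el[is.na(el) | el == ""] <-
    toupper(substr(gsub("[0-9'\"]", "", model$elety[is.na(el) | el == ""]), 1, 1))
  r <- unname(table[el])
  r[is.na(r)] <- default
  r
}

#' Radius-threshold conductance rule
#'
#' Classification thresholds on the minimum gate radius: non-conducting
#' C up to the water radius, first open level O1 up to the second
#' threshold, O2 beyond it.
#'
#' @param water_radius Upper bound of C (default 1.4 Angstrom, the
#'   radius of a water molecule).
#' @param o1_upper Upper bound of O1 (default 2.3 Angstrom).
#' @export
radius_state_rule <- function(water_radius = 1.4, o1_upper = 2.3) {
  if (!(0 < water_radius && water_radius < o1_upper))
    stop("radius_state_rule: need 0 < water_radius < o1_upper")
  structure(list(water_radius = water_radius, o1_upper = o1_upper),
            class = "radius_state_rule")
}

#' Classify a minimum gate radius into a conductance state
#'
#' C if `rmin <= water_radius`; O1 if in `(water_radius, o1_upper]`;
#' O2 if above `o1_upper`.  Boundaries are inclusive on the lower
#' state.
#'
#' @param rmin_gate Minimum pore radius over the gate window (Angstrom,
#'   >= 0).
#' @param rule A [radius_state_rule()].
#' @return Character: "C", "O1" or "O2" (vectorised).
#' @export
classify_conductance <- function(rmin_gate, rule = radius_state_rule()) {
  if (any(rmin_gate < 0)) stop("classify_conductance: negative radius")
  ifelse(rmin_gate <= rule$water_radius, "C",
         ifelse(rmin_gate <= rule$o1_upper, "O1", "O2"))
}

# Largest clearance of a sphere centred at (cx, cy, z): min over atoms
# of (distance to atom centre - atom vdW radius).  `xyz` n x 3, `rad`
# length n.
.clearance <- function(cx, cy, z, xyz, rad) {
  d <- sqrt((xyz[, 1] - cx)^2 + (xyz[, 2] - cy)^2 + (xyz[, 3] - z)^2) - rad
  min(d)
}

#' Inscribed-sphere pore-radius profile along the z axis
#'
#' For each grid position z, finds the sphere centre in that plane
#' (within `lateral_bound` of the axis) maximising the clearance to all
#' atom van der Waals surfaces, by a deterministic coarse-to-fine grid
#' search followed by a Nelder-Mead polish.  The radius is capped at
#' `cap` where the pore is locally unbounded; if no atoms fall within
#' reach of a plane the capped radius is reported with a warning.
#'
#' @param model A [structure_model()] aligned to the gate frame.
#' @param z_range Length-2 axial interval (Angstrom).
#' @param step Axial grid spacing (Angstrom).
#' @param lateral_bound Half-width of the sphere-centre search box
#'   around the axis (Angstrom).
#' @param grid Fine lateral grid spacing (Angstrom).
#' @param cap Radius cap for locally unbounded planes (Angstrom).
#' @param radii Per-atom vdW radii; default [vdw_radii()].
#' @param gate_window,filter_window Optional z-intervals over which the
#'   windowed minima `rmin_gate` / `rmin_filter` are taken; the gate
#'   window defaults to the z-span of the T617-T625 CA atoms (when
#'   those residues are present) and the filter window to the z-span of
#'   residues 586-590 backbone.
#' @return Object of class `pore_profile`: data.frame (z, radius) plus
#'   `rmin_gate`, `rmin_filter` and the windows used.
#' @export
pore_radius_profile <- function(model, z_range = NULL, step = 0.25,
                                lateral_bound = 5, grid = 0.1, cap = 10,
                                radii = vdw_radii(model),
                                gate_window = NULL, filter_window = NULL) {
  xyz <- atom_coords(model)
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  zg <- seq(z_range[1], z_range[2], by = step)
  maxr <- max(radii)
  rad_out <- numeric(length(zg))
  warned <- FALSE
  for (k in seq_along(zg)) {
    z <- zg[k]
    sel <- abs(xyz[, 3] - z) < cap + maxr
    if (!any(sel)) {
      if (!warned) {
        warning("pore_radius_profile: no atoms near z = ", round(z, 2),
                "; radius capped at ", cap)
        warned <- TRUE
      }
      rad_out[k] <- cap
      next
    }
    a <- xyz[sel, , drop = FALSE]
    r <- radii[sel]
    # coarse grid (1 A), then fine grid around the best coarse point
    best <- c(0, 0); bestv <- .clearance(0, 0, z, a, r)
    for (cx in seq(-lateral_bound, lateral_bound, by = 1)) {
      for (cy in seq(-lateral_bound, lateral_bound, by = 1)) {
        v <- .clearance(cx, cy, z, a, r)
        if (v > bestv) { bestv <- v; best <- c(cx, cy) }
      }
    }
    for (cx in seq(best[1] - 1, best[1] + 1, by = grid)) {
      for (cy in seq(best[2] - 1, best[2] + 1, by = grid)) {
        v <- .clearance(cx, cy, z, a, r)
        if (v > bestv) { bestv <- v; best <- c(cx, cy) }
      }
    }
    op <- stats::optim(best, function(p) -.clearance(p[1], p[2], z, a, r),
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 400))
    rad_out[k] <- min(max(bestv, -op$value), cap)
  }
  prof <- data.frame(z = zg, radius = rad_out)
  win_span <- function(resnos, etys) {
    i <- which(model$resno %in% resnos & model$elety %in% etys)
    if (!length(i)) return(NULL)
    range(xyz[i, 3])
  }
  if (is.null(gate_window))
    gate_window <- win_span(617:625, "CA")
  if (is.null(filter_window))
    filter_window <- win_span(586:590, c("N", "CA", "C", "O"))
  rmin_in <- function(win) {
    if (is.null(win)) return(NA_real_)
    sel <- prof$z >= win[1] & prof$z <= win[2]
    if (!any(sel)) return(NA_real_)
    min(prof$radius[sel])
  }
  structure(list(profile = prof,
                 rmin_gate = rmin_in(gate_window),
                 rmin_filter = rmin_in(filter_window),
                 gate_window = gate_window,
                 filter_window = filter_window),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("pore_profile: %d z-points in [%.1f, %.1f] A\n",
              nrow(x$profile), min(x$profile$z), max(x$profile$z)))
  if (!is.na(x$rmin_gate))
    cat(sprintf("  rmin (gate window %.1f..%.1f A): %.2f A -> %s\n",
                x$gate_window[1], x$gate_window[2], x$rmin_gate,
                classify_conductance(x$rmin_gate)))
  if (!is.na(x$rmin_filter))
    cat(sprintf("  rmin (filter window %.1f..%.1f A): %.2f A\n",
                x$filter_window[1], x$filter_window[2], x$rmin_filter))
  invisible(x)
}
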