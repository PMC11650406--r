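# Parametric catheter electrode sets rasterized in ideal tangential contact
# with the phantom wall, plus their vectoring schemes.
#
# All electrodes are placed in blood voxels adjacent to the endocardial
# surface (no tissue displacement), conforming to the wall: on the antrum
# phantom, electrode positions are expressed in surface coordinates
# (s = arc length along the circumference at the vein radius, a = axial
# offset from the band center, depth = distance from the wall into the
# lumen); on the slab the same frame maps to (x, y, height above the wall).
# Thin struts (0.127 mm) are rasterized to chains at least one voxel wide;
# the ECD denominator always uses the analytic metal area, never the
# inflated voxel area.

CATHETER_DESIGNS <- c("circular", "penta_spline", "flex_splines", "balloon",
                      "focal_sphere_9mm", "oneshot_sphere")

PUBLISHED_VECTOR_COUNTS <- c(oneshot_sphere = 3L, focal_sphere_9mm = 7L,
                       penta_spline = 6L, circular = 3L,
                       flex_splines = 8L, balloon = 8L)

default_catheter_params <- function(design) {
  switch(design,
    circular = list(n_electrodes = 10L, electrode_length_mm = 3,
                    electrode_diameter_mm = 1.6, gap_mm = 3.7),
    penta_spline = list(n_splines = 5L, rings_per_spline = 4L,
                        ring_diameter_mm = 1.3, ring_length_mm = 3,
                        ring_gaps_mm = c(3, 3, 4), rotation_deg = 36),
    flex_splines = ,
    balloon = list(n_splines = 4L, electrode_mm = 3.6,
                   electrode_spacing_mm = 6, electrodes_per_spline = 3L,
                   spline_width_mm = 4, rotation_deg = 45,
                   balloon_halflength_mm = 12),
    focal_sphere_9mm = list(sphere_diameter_mm = 9, flat_cap_diameter_mm = 6,
                            strut_width_mm = 0.127, n_meridians = 12L,
                            parallel_step_deg = 30, cap_ring_step_mm = 1.5,
                            cap_n_spokes = 8L, placement_step_mm = 6,
                            n_placements = 7L, patch_size_mm = 60,
                            center_offset_mm = 0),
    oneshot_sphere = list(sphere_diameter_mm = 30, n_panels = 6L,
                          panel_height_mm = NA, diamond_pitch_mm = NA,
                          strut_width_mm = 0.127, joint_gap_mm = 1,
                          panel_width_mm = NA, patch_size_mm = 60),
    stop("unknown catheter design: ", design))
}

# Surface coordinate frame over the phantom.
surface_frame <- function(grid) {
  p <- grid$params
  dims <- dim(grid$labels)
  co <- grid_coordinates(dims, grid$spacing_mm, grid$origin_mm)
  blood <- grid$labels == grid$label_names[["blood"]]
  if (grid$kind == "antrum") {
    rv <- p$vein_radius_mm
    rho <- sqrt(co$x^2 + co$y^2)
    list(S = atan2(co$x, co$y) * rv, A = co$z - p$band_z_mm, D = rv - rho,
         blood = blood, C = 2 * pi * rv, co = co, grid = grid)
  } else {
    ex <- p$extent_mm
    list(S = co$x - ex[1] / 2, A = co$y - ex[2] / 2,
         D = co$z - (p$base_mm + p$wall_mm),
         blood = blood, C = Inf, co = co, grid = grid)
  }
}

arc_dist <- function(frame, s0) {
  if (is.finite(frame$C)) ((frame$S - s0 + frame$C / 2) %% frame$C) - frame$C / 2
  else frame$S - s0
}

new_electrode <- function(name, idx, area_cm2, center_s = NA, center_a = NA) {
  if (length(idx) == 0L)
    stop("electrode '", name,
         "' rasterized to an empty mask: spacing too coarse for this design")
  list(name = name, idx = as.integer(idx), area_cm2 = area_cm2,
       center_s = center_s, center_a = center_a)
}

# --- per-design builders ----------------------------------------------------

build_circular <- function(frame, p, h) {
  r_ax <- p$electrode_diameter_mm / 2
  L <- p$electrode_length_mm
  if (is.finite(frame$C)) {
    pitch <- min(L + p$gap_mm, frame$C / p$n_electrodes)
    centers <- (seq_len(p$n_electrodes) - 1) * pitch
    centers <- centers - mean(centers)  # centred on the posterior band
  } else {
    pitch <- L + p$gap_mm
    centers <- ((seq_len(p$n_electrodes) - 1) - (p$n_electrodes - 1) / 2) * pitch
  }
  if (pitch - L < h)
    stop("spacing too coarse to separate adjacent ring electrodes")
  area <- pi * p$electrode_diameter_mm * L / 100
  lapply(seq_along(centers), function(j) {
    ds <- arc_dist(frame, centers[j])
    sel <- which(frame$blood & abs(ds) <= L / 2 &
                   (frame$A^2 + (frame$D - r_ax)^2) <= max(r_ax, 0.75 * h)^2)
    new_electrode(sprintf("ring_%02d", j), sel, area, centers[j], 0)
  })
}

build_penta <- function(frame, p, h) {
  rv <- frame$grid$params$vein_radius_mm
  r_ring <- p$ring_diameter_mm / 2
  L <- p$ring_length_mm
  # ring centres along the spline (axial), centred on the band
  z_off <- cumsum(c(0, p$ring_gaps_mm + L))
  z_off <- z_off - mean(z_off)
  area <- p$rings_per_spline * pi * p$ring_diameter_mm * L / 100
  els <- list()
  for (app in 1:2) {
    rot <- if (app == 2) p$rotation_deg * pi / 180 * rv else 0
    for (j in seq_len(p$n_splines)) {
      s0 <- ((j - 1) * frame$C / p$n_splines + rot + frame$C / 2) %% frame$C -
        frame$C / 2
      ds <- arc_dist(frame, s0)
      sel <- integer(0)
      for (z0 in z_off) {
        sel <- c(sel, which(frame$blood & abs(frame$A - z0) <= L / 2 &
                              (ds^2 + (frame$D - r_ring)^2) <=
                              max(r_ring, 0.75 * h)^2))
      }
      els[[length(els) + 1L]] <-
        new_electrode(sprintf("spline_a%d_%d", app, j), unique(sel),
                      area, s0, 0)
    }
  }
  els
}

build_flex <- function(frame, p, h) {
  e <- p$electrode_mm
  area <- e^2 / 100
  a_off <- (seq_len(p$electrodes_per_spline) -
              (p$electrodes_per_spline + 1) / 2) * p$electrode_spacing_mm
  els <- list()
  for (app in 1:2) {
    rot <- if (app == 2) p$rotation_deg * pi / 180 else 0
    rv_arc <- if (is.finite(frame$C)) frame$C / (2 * pi) else NA
    for (j in seq_len(p$n_splines)) {
      s0 <- if (is.finite(frame$C)) {
        (((j - 1) * 2 * pi / p$n_splines + rot) * rv_arc + frame$C / 2) %%
          frame$C - frame$C / 2
      } else {
        ((j - 1) - (p$n_splines - 1) / 2) * 10 + rot * 5
      }
      ds <- arc_dist(frame, s0)
      for (k in seq_along(a_off)) {
        sel <- which(frame$blood & abs(ds) <= max(e / 2, 0.55 * h) &
                       abs(frame$A - a_off[k]) <= max(e / 2, 0.55 * h) &
                       frame$D >= 0 & frame$D <= max(h, 1) * 1.001)
        els[[length(els) + 1L]] <-
          new_electrode(sprintf("spline_a%d_%d_e%d", app, j, k), sel,
                        area, s0, a_off[k])
      }
    }
  }
  els
}

build_focal_sphere <- function(frame, p, h) {
  grid <- frame$grid
  if (grid$kind != "antrum")
    stop("the focal sphere model is placed on the antrum phantom")
  gp <- grid$params
  rv <- gp$vein_radius_mm
  r_s <- p$sphere_diameter_mm / 2
  cap_r <- p$flat_cap_diameter_mm / 2
  d_f <- sqrt(r_s^2 - cap_r^2)    # centre-to-contact-plane distance
  alpha0 <- p$center_offset_mm / rv
  ctr <- c(sin(alpha0) * (rv - d_f), cos(alpha0) * (rv - d_f), gp$band_z_mm)
  n_hat <- c(sin(alpha0), cos(alpha0), 0)
  u_hat <- c(cos(alpha0), -sin(alpha0), 0)

  px <- frame$co$x - ctr[1]; py <- frame$co$y - ctr[2]; pz <- frame$co$z - ctr[3]
  r_loc <- sqrt(px^2 + py^2 + pz^2)
  cth <- (px * n_hat[1] + py * n_hat[2]) / pmax(r_loc, 1e-9)
  theta <- acos(pmin(pmax(cth, -1), 1))
  phi <- atan2(pz, px * u_hat[1] + py * u_hat[2])

  dth <- p$parallel_step_deg * pi / 180
  w_ang <- 0.55 * h / r_s
  near_parallel <- abs(theta - round(theta / dth) * dth) <= w_ang
  dphi <- 2 * pi / p$n_meridians
  near_meridian <- abs(phi - round(phi / dphi) * dphi) * pmax(sin(theta), 1e-6) <=
    w_ang
  cage <- frame$blood & abs(r_loc - r_s) <= 0.55 * h & frame$D > h &
    (near_parallel | near_meridian)

  ds <- arc_dist(frame, p$center_offset_mm)
  lat <- sqrt(ds^2 + frame$A^2)
  ring_step <- p$cap_ring_step_mm
  near_ring <- abs(lat - round(lat / ring_step) * ring_step) <= 0.55 * h
  phic <- atan2(frame$A, ds)
  dsp <- 2 * pi / p$cap_n_spokes
  near_spoke <- abs(phic - round(phic / dsp) * dsp) * lat <= 0.55 * h
  cap <- frame$blood & frame$D >= 0 & frame$D <= h * 1.001 & lat <= cap_r &
    (near_ring | near_spoke)

  # analytic outer metal area of the whole cage (Faraday-shielded inner
  # surfaces excluded): half the lateral surface of round wire struts
  l_mer <- p$n_meridians * pi * r_s
  th <- seq(dth, pi - 1e-9, by = dth)
  l_par <- sum(2 * pi * r_s * sin(th))
  rr <- seq(ring_step, cap_r, by = ring_step)
  l_cap <- sum(2 * pi * rr) + p$cap_n_spokes * cap_r
  area <- (l_mer + l_par + l_cap) * (pi * p$strut_width_mm / 2) / 100

  list(new_electrode("cage", which(cage | cap), area, p$center_offset_mm, 0))
}

build_oneshot <- function(frame, p, h) {
  # undeformed panel size on the deployed sphere: one of n_panels lunes
  w_phys <- pi * p$sphere_diameter_mm / p$n_panels
  if (is.finite(frame$C)) {
    W <- if (is.na(p$panel_width_mm)) frame$C / p$n_panels - p$joint_gap_mm
         else p$panel_width_mm
    centers <- (seq_len(p$n_panels) - 1) * frame$C / p$n_panels
    centers <- ((centers + frame$C / 2) %% frame$C) - frame$C / 2
  } else {
    W <- if (is.na(p$panel_width_mm)) 12 else p$panel_width_mm
    centers <- ((seq_len(p$n_panels) - 1) - (p$n_panels - 1) / 2) *
      (W + p$joint_gap_mm)
    ext <- frame$grid$params$extent_mm
    if (max(abs(centers)) + W / 2 > ext[1] / 2)
      stop("oneshot panel footprint exceeds the phantom")
  }
  H <- if (is.na(p$panel_height_mm)) w_phys else p$panel_height_mm
  pitch <- if (is.na(p$diamond_pitch_mm)) w_phys / 3 else p$diamond_pitch_mm
  # the sphere touches the wall along its equatorial contact line; away from
  # it the panel stands off the wall with the sphere's sagitta
  r_s <- p$sphere_diameter_mm / 2
  standoff <- function(a) pmin(a^2 / (2 * r_s), r_s)

  # analytic single-panel metal area from the physical (undeformed) panel:
  # strut length density of the two diagonal families is 2*sqrt(2)/pitch
  a_panel <- pi * p$sphere_diameter_mm^2 / p$n_panels
  l_strut <- a_panel * 2 * sqrt(2) / pitch + 4 * sqrt(a_panel)
  area <- l_strut * p$strut_width_mm / 100

  wtol <- 0.55 * h
  lapply(seq_along(centers), function(j) {
    ds <- arc_dist(frame, centers[j])
    u <- ds + frame$A
    w <- ds - frame$A
    du <- abs(((u + pitch / 2) %% pitch) - pitch / 2) / sqrt(2)
    dw <- abs(((w + pitch / 2) %% pitch) - pitch / 2) / sqrt(2)
    frame_line <- (abs(abs(ds) - W / 2) <= wtol) | (abs(abs(frame$A) - H / 2) <= wtol)
    so <- standoff(frame$A)
    sel <- which(frame$blood & abs(ds) <= W / 2 + wtol & abs(frame$A) <= H / 2 + wtol &
                   frame$D >= so & frame$D <= so + h * 1.001 &
                   (du <= wtol | dw <= wtol | frame_line))
    new_electrode(sprintf("panel_%d", j), sel, area, centers[j], 0)
  })
}

build_return_patch <- function(grid, size_mm) {
  dims <- dim(grid$labels)
  co <- grid_coordinates(dims, grid$spacing_mm, grid$origin_mm)
  if (grid$kind == "antrum") {
    # boundary face farthest from the posterior (+y) target
    sel <- which(slice.index(grid$labels, 2) == 1L &
                   abs(co$x) <= size_mm / 2 &
                   abs(co$z - grid$params$band_z_mm) <= size_mm / 2)
  } else {
    ex <- grid$params$extent_mm
    sel <- which(slice.index(grid$labels, 3) == 1L &
                   abs(co$x - ex[1] / 2) <= size_mm / 2 &
                   abs(co$y - ex[2] / 2) <= size_mm / 2)
  }
  list(name = "patch", idx = as.integer(sel), area_cm2 = size_mm^2 / 100)
}

# ---------------------------------------------------------------------------

#' Build a voxelized catheter electrode set
#'
#' Rasterizes the electrodes of one of the six catheter designs onto the
#' endocardial surface over the target band, in ideal tangential contact
#' (electrode voxels lie in blood, adjacent to but never inside the wall).
#' Monopolar designs (`focal_sphere_9mm`, `oneshot_sphere`) also get a
#' return patch on the phantom boundary face farthest from the target; the
#' balloon additionally fills the lumen behind its electrodes with insulator
#' voxels.
#'
#' Default dimensions: circular decapolar with 3 mm x 1.6 mm rings at
#' 3.7 mm gaps; penta-spline with 5 splines of four 1.3 mm x 3 mm rings
#' (gaps 3/3/4 mm) and a second application rotated 36 degrees; flex
#' splines/balloon with 3.6 x 3.6 mm electrodes every 6 mm on 4 mm splines
#' and a second application rotated 45 degrees; focal 9 mm Nitinol mesh
#' sphere (0.127 mm struts) with a 6 mm flattened contact cap, applied 7
#' times at 6 mm steps; large one-shot sphere of six diamond-mesh panels
#' (nominal 30 mm deployment) conforming to the antrum circumference.
#'
#' @param design one of `r paste(CATHETER_DESIGNS, collapse = ", ")`.
#' @param grid an `anatomy_grid`.
#' @param target a `target_region` on `grid`.
#' @param params named overrides of the design defaults.
#' @return object of class `electrode_set`: `electrodes` (named list of
#'   `{name, idx, area_cm2}`), optional `return_patch`, optional
#'   `insulator_idx`, `design`, resolved `params`.
#' @export
build_catheter <- function(design, grid, target, params = list()) {
  if (length(design) != 1L || !design %in% CATHETER_DESIGNS)
    stop("unknown catheter design: ", paste(design, collapse = ", "))
  p <- modifyList(default_catheter_params(design), params)
  h <- grid$spacing_mm
  frame <- surface_frame(grid)

  els <- switch(design,
                circular = build_circular(frame, p, h),
                penta_spline = build_penta(frame, p, h),
                flex_splines = build_flex(frame, p, h),
                balloon = build_flex(frame, p, h),
                focal_sphere_9mm = build_focal_sphere(frame, p, h),
                oneshot_sphere = build_oneshot(frame, p, h))
  names(els) <- vapply(els, `[[`, character(1), "name")

  all_idx <- unlist(lapply(els, `[[`, "idx"))
  if (anyDuplicated(all_idx))
    stop("electrode masks overlap: spacing too coarse to separate electrodes")
  if (any(grid$labels[all_idx] == grid$label_names[["myocardium"]]))
    stop("internal error: electrode voxels inside myocardium")

  monopolar <- design %in% c("focal_sphere_9mm", "oneshot_sphere")
  patch <- if (monopolar) build_return_patch(grid, p$patch_size_mm %||% 50)
           else NULL

  insulator_idx <- NULL
  if (design == "balloon") {
    insulator_idx <- setdiff(
      which(frame$blood & abs(frame$A) <= p$balloon_halflength_mm &
              frame$D > 0),
      all_idx)
  }

  set <- structure(list(design = design, electrodes = els,
                        return_patch = patch, insulator_idx = insulator_idx,
                        params = p, spacing_mm = h),
                   class = "electrode_set")
  set
}

#' @export
print.electrode_set <- function(x, ...) {
  nv <- vapply(x$electrodes, function(e) length(e$idx), integer(1))
  cat(sprintf("<electrode_set> %s: %d electrode(s), %d voxels total%s%s\n",
              x$design, length(x$electrodes), sum(nv),
              if (!is.null(x$return_patch)) ", return patch" else "",
              if (!is.null(x$insulator_idx))
                sprintf(", %d insulator voxels", length(x$insulator_idx))
              else ""))
  invisible(x)
}

electrode_indices <- function(electrodes, name) {
  if (name == "patch") {
    if (is.null(electrodes$return_patch)) stop("design has no return patch")
    return(electrodes$return_patch$idx)
  }
  e <- electrodes$electrodes[[name]]
  if (is.null(e)) stop("unknown electrode: ", name)
  e$idx
}

#' Relabel balloon insulator voxels
#'
#' @param grid an `anatomy_grid`.
#' @param electrodes an `electrode_set` (only the balloon carries
#'   insulator voxels; other designs return the grid unchanged).
#' @return the grid with insulator voxels relabeled `balloon_insulator`.
#' @export
apply_insulators <- function(grid, electrodes) {
  if (is.null(electrodes$insulator_idx) || !length(electrodes$insulator_idx))
    return(grid)
  grid$labels[electrodes$insulator_idx] <-
    grid$label_names[["balloon_insulator"]]
  grid
}

#' Vectoring scheme for a design
#'
#' Returns the ordered list of energy deliveries with polarity assignments.
#' A "vector" is one positive (sourcing) electrode with its return; the
#' number of vectors counted on target follows the published per-design
#' accounting (one-shot 3, focal sphere 7, penta-spline 6, circular 3,
#' flex/balloon 8): deliveries whose sourcing electrode is nearest the band
#' center are flagged `counted`.
#'
#' Vectoring: circular fires once with interlaced alternating +/- rings;
#' penta-spline fires spline-to-adjacent-spline bipoles rotating five times
#' per application, two applications; flex/balloon fire one axial tripole
#' (-,+,-) per spline, four splines, two applications; the spheres fire
#' monopolar to the return patch, the focal sphere once per placement (7
#' placements at 6 mm steps), the one-shot once per panel.
#'
#' @param design design name.
#' @param electrodes the matching `electrode_set`.
#' @return object of class `vector_scheme`: `deliveries` (each with `name`,
#'   `polarity` map, `counted`, `n_vectors_on_target`,
#'   `placement_offset_mm`), `n_counted_vectors`.
#' @export
make_vector_scheme <- function(design, electrodes) {
  if (length(design) != 1L || !design %in% CATHETER_DESIGNS)
    stop("unknown catheter design: ", paste(design, collapse = ", "))
  stopifnot(inherits(electrodes, "electrode_set"),
            electrodes$design == design)
  els <- electrodes$electrodes
  deliveries <- list()

  if (design == "circular") {
    ord <- order(vapply(els, `[[`, numeric(1), "center_s"))
    pol <- rep_len(c(1, -1), length(els))
    names(pol) <- names(els)[ord]
    deliveries[[1]] <- list(name = "interlaced", polarity = pol,
                            counted = TRUE,
                            n_vectors_on_target = PUBLISHED_VECTOR_COUNTS[[design]],
                            placement_offset_mm = 0)
  } else if (design == "penta_spline") {
    n <- electrodes$params$n_splines
    cen <- vapply(els, `[[`, numeric(1), "center_s")
    cand <- list()
    for (app in 1:2) for (j in seq_len(n)) {
      a <- sprintf("spline_a%d_%d", app, j)
      b <- sprintf("spline_a%d_%d", app, j %% n + 1L)
      pol <- c(1, -1); names(pol) <- c(a, b)
      cand[[length(cand) + 1L]] <-
        list(name = sprintf("bipole_a%d_%d", app, j), polarity = pol,
             counted = FALSE, n_vectors_on_target = 0L,
             placement_offset_mm = 0, anode_s = cen[[a]])
    }
    keep <- order(abs(vapply(cand, `[[`, numeric(1), "anode_s")))[
      seq_len(PUBLISHED_VECTOR_COUNTS[[design]])]
    for (i in keep) {
      cand[[i]]$counted <- TRUE
      cand[[i]]$n_vectors_on_target <- 1L
    }
    deliveries <- cand
  } else if (design %in% c("flex_splines", "balloon")) {
    p <- electrodes$params
    for (app in 1:2) for (j in seq_len(p$n_splines)) {
      nm <- sprintf("spline_a%d_%d_e%d", app, j,
                    seq_len(p$electrodes_per_spline))
      mid <- ceiling(p$electrodes_per_spline / 2)
      pol <- rep(-1, p$electrodes_per_spline)
      pol[mid] <- 1
      names(pol) <- nm
      deliveries[[length(deliveries) + 1L]] <-
        list(name = sprintf("tripole_a%d_%d", app, j), polarity = pol,
             counted = TRUE, n_vectors_on_target = 1L,
             placement_offset_mm = 0)
    }
  } else if (design == "focal_sphere_9mm") {
    p <- electrodes$params
    off <- (seq_len(p$n_placements) - (p$n_placements + 1) / 2) *
      p$placement_step_mm
    for (i in seq_along(off)) {
      pol <- c(cage = 1, patch = -1)
      deliveries[[length(deliveries) + 1L]] <-
        list(name = sprintf("placement_%d", i), polarity = pol,
             counted = TRUE, n_vectors_on_target = 1L,
             placement_offset_mm = off[i])
    }
  } else { # oneshot_sphere
    cen <- vapply(els, `[[`, numeric(1), "center_s")
    keep <- names(sort(abs(cen)))[seq_len(PUBLISHED_VECTOR_COUNTS[[design]])]
    for (nm in names(els)) {
      pol <- c(1, -1); names(pol) <- c(nm, "patch")
      deliveries[[length(deliveries) + 1L]] <-
        list(name = nm, polarity = pol, counted = nm %in% keep,
             n_vectors_on_target = if (nm %in% keep) 1L else 0L,
             placement_offset_mm = 0)
    }
  }

  structure(list(design = design, deliveries = deliveries,
                 n_counted_vectors = sum(vapply(deliveries, `[[`, integer(1),
                                                "n_vectors_on_target"))),
            class = "vector_scheme")
}

#' @export
print.vector_scheme <- function(x, ...) {
  cat(sprintf("<vector_scheme> %s: %d deliveries, %d counted on target\n",
              x$design, length(x$deliveries),
              sum(vapply(x$deliveries, `[[`, logical(1), "counted"))))
  invisible(x)
}

# Electrode set to use for one delivery: multi-placement designs (focal
# sphere) are rebuilt at the delivery's arc offset; static designs reuse the
# built set.
electrodes_for_delivery <- function(electrodes, grid, target, delivery) {
  off <- delivery$placement_offset_mm %||% 0
  if (off == 0) return(electrodes)
  build_catheter(electrodes$design, grid, target,
                 modifyList(electrodes$params, list(center_offset_mm = off)))
}

#' ECD denominator metal area
#'
#' Per-design electrode area convention for the electrode current density:
#' whole cage for the focal 9 mm sphere (inner surfaces excluded), one
#' diamond panel for the one-shot sphere, the total electrode area of one
#' spline for the penta-spline, and the area of a single electrode for the
#' bipolar designs.  Areas are analytic (cylinder/plate/strut formulas from
#' the design dimensions), not voxel-counted.
#'
#' @param design design name.
#' @param electrodes the matching `electrode_set`.
#' @return area in cm^2.
#' @export
electrode_metal_area <- function(design, electrodes) {
  design <- match.arg(design, CATHETER_DESIGNS)
  stopifnot(electrodes$design == design)
  electrodes$electrodes[[1]]$area_cm2
}
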