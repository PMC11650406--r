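# Synthetic voxel phantoms: a validation slab and an idealized left
# pulmonary vein (LPV) antrum (blood-filled cylindrical vein opening into a
# larger blood chamber, wrapped by a 2.5 mm myocardial shell, embedded in
# connective background).  The antrum geometry is defined by an exact signed
# distance to the blood pool, so the shell has the nominal thickness along
# every surface normal by construction.

TISSUE_CLASSES <- c(blood = 1L, myocardium = 2L, connective_background = 3L,
                    balloon_insulator = 4L, electrode_metal = 5L,
                    domain_boundary_patch = 6L)

default_phantom_params <- function(kind) {
  switch(kind,
         slab = list(extent_mm = c(40, 40, 20), wall_mm = 2.5, base_mm = 5),
         antrum = list(extent_mm = c(64, 64, 72), vein_radius_mm = 10,
                       wall_mm = 2.5, chamber_radius_mm = 20,
                       chamber_center_z_mm = 18, band_z_mm = 40))
}

# Voxel-center coordinate arrays (mm).  Physical position of voxel (i,j,k)
# (1-based) is origin + (index - 0.5) * spacing.
grid_coordinates <- function(dims, spacing_mm, origin_mm) {
  ax <- lapply(1:3, function(a) origin_mm[a] + (seq_len(dims[a]) - 0.5) * spacing_mm)
  list(x = array(ax[[1]], dims),
       y = array(rep(ax[[2]], each = dims[1]), dims),
       z = array(rep(ax[[3]], each = dims[1] * dims[2]), dims),
       axes = ax)
}

#' Build a labeled voxel phantom
#'
#' Two phantom kinds are supported: `"slab"` (a flat myocardial plate of
#' configurable thickness over connective background, blood above; used for
#' solver validation) and `"antrum"` (a blood-filled cylindrical vein of
#' default radius 10 mm opening into a larger spherical blood chamber,
#' separated from background by a myocardial shell of default thickness
#' 2.5 mm).  The antrum stands in for a CT-derived atrial geometry while
#' preserving the features the outcome metrics depend on: wall curvature,
#' blood pool, wall thickness and a distant return path.
#'
#' @param kind `"slab"` or `"antrum"`.
#' @param params named list overriding the geometry defaults
#'   (`extent_mm`, `wall_mm`; slab: `base_mm`; antrum: `vein_radius_mm`,
#'   `chamber_radius_mm`, `chamber_center_z_mm`, `band_z_mm`).
#' @param spacing_mm isotropic voxel spacing in \[0.1, 1\] mm; must resolve
#'   the wall with at least 2 voxels.
#' @return object of class `anatomy_grid`: integer `labels` array,
#'   `spacing_mm`, `origin_mm`, `label_names`, `kind`, resolved `params`.
#' @export
build_phantom <- function(kind = c("slab", "antrum"), params = list(),
                          spacing_mm = 0.5) {
  kind <- match.arg(kind)
  if (spacing_mm < 0.1 - 1e-9 || spacing_mm > 1.0 + 1e-9)
    stop("spacing_mm must be in [0.1, 1.0] mm")
  p <- modifyList(default_phantom_params(kind), params)
  if (p$wall_mm / spacing_mm < 2 - 1e-9)
    stop("spacing cannot resolve the wall with at least 2 voxels")
  if (any(p$extent_mm <= 0)) stop("phantom extent must be positive")
  if (kind == "antrum" && any(p$extent_mm < 60 - 1e-9))
    stop("antrum phantom extent must be at least 60 mm per axis")

  dims <- as.integer(round(p$extent_mm / spacing_mm))
  extent <- dims * spacing_mm  # realized extent covers the grid exactly
  origin <- if (kind == "antrum") c(-extent[1] / 2, -extent[2] / 2, 0)
            else c(0, 0, 0)
  co <- grid_coordinates(dims, spacing_mm, origin)

  lab <- array(TISSUE_CLASSES[["connective_background"]], dims)
  if (kind == "slab") {
    z <- co$z
    lab[z > p$base_mm & z <= p$base_mm + p$wall_mm] <-
      TISSUE_CLASSES[["myocardium"]]
    lab[z > p$base_mm + p$wall_mm] <- TISSUE_CLASSES[["blood"]]
  } else {
    rho <- sqrt(co$x^2 + co$y^2)
    zc <- p$chamber_center_z_mm
    d_sph <- sqrt(rho^2 + (co$z - zc)^2) - p$chamber_radius_mm
    d_cyl <- rho - p$vein_radius_mm
    below <- co$z < zc
    d_cyl[below] <- sqrt(pmax(d_cyl[below], 0)^2 + (zc - co$z[below])^2)
    d <- pmin(d_sph, d_cyl)
    lab[d <= p$wall_mm] <- TISSUE_CLASSES[["myocardium"]]
    lab[d < 0] <- TISSUE_CLASSES[["blood"]]
  }

  structure(list(labels = lab, spacing_mm = spacing_mm, origin_mm = origin,
                 label_names = TISSUE_CLASSES, kind = kind, params = p),
            class = "anatomy_grid")
}

#' @export
print.anatomy_grid <- function(x, ...) {
  d <- dim(x$labels)
  counts <- table(factor(x$labels, levels = x$label_names,
                         labels = names(x$label_names)))
  cat(sprintf("<anatomy_grid> %s phantom, %d x %d x %d voxels at %.3g mm\n",
              x$kind, d[1], d[2], d[3], x$spacing_mm))
  cat("  voxels per class:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

label_mask_idx <- function(grid, class) {
  which(grid$labels == grid$label_names[[class]])
}

# Wall thickness (mm) along a radial surface normal through the antrum
# shell at azimuth alpha (radians from +y) and height z: the length of the
# ray inside myocardium-labeled voxels.  (Length, not crossed-voxel count:
# a diagonal ray crosses up to ~1.4x more voxels than its length covers.)
probe_wall_thickness <- function(grid, alpha, z) {
  stopifnot(grid$kind == "antrum")
  p <- grid$params
  h <- grid$spacing_mm
  step <- h / 8
  rmax <- p$vein_radius_mm + p$wall_mm + 3
  rr <- seq(0, rmax, by = step)
  pts <- cbind(rr * sin(alpha), rr * cos(alpha), z)
  ijk <- sweep(pts, 2, grid$origin_mm) / h
  ijk <- pmin(pmax(ceiling(ijk), 1),
              matrix(dim(grid$labels), nrow(ijk), 3, byrow = TRUE))
  lin <- ijk[, 1] + dim(grid$labels)[1] *
    ((ijk[, 2] - 1) + dim(grid$labels)[2] * (ijk[, 3] - 1))
  step * sum(grid$labels[lin] == grid$label_names[["myocardium"]])
}

#' Define the target band
#'
#' Marks the full-thickness wall voxels of a circumferential band on the
#' posterior vein wall of the antrum phantom (or a rectangular band on the
#' slab): band of the stated arc length along the circumference and the
#' stated width along the vein axis.  The default 6 x 47 mm band on a 2.5 mm
#' wall has nominal volume 705 mm^3.
#'
#' @param grid an `anatomy_grid`.
#' @param band_length_mm arc length of the band along the circumference
#'   (measured at mid-wall radius), mm.
#' @param band_width_mm axial width of the band, mm.
#' @return object of class `target_region`: logical `mask`, integer `idx`,
#'   `nominal_dims_mm`, `volume_mm3`.
#' @export
define_target <- function(grid, band_length_mm = 47, band_width_mm = 6) {
  if (band_width_mm <= 0) stop("band width must be positive")
  if (band_length_mm <= 0) stop("band length must be positive")
  p <- grid$params
  h <- grid$spacing_mm
  dims <- dim(grid$labels)
  co <- grid_coordinates(dims, h, grid$origin_mm)
  myo <- grid$labels == grid$label_names[["myocardium"]]

  if (grid$kind == "antrum") {
    r_mid <- p$vein_radius_mm + p$wall_mm / 2
    if (band_length_mm > 2 * pi * r_mid + 1e-9)
      stop("band longer than the available circumference")
    alpha_half <- (band_length_mm / 2) / r_mid
    alpha <- atan2(co$x, co$y)  # 0 at +y (posterior)
    mask <- myo &
      abs(co$z - p$band_z_mm) <= band_width_mm / 2 &
      abs(alpha) <= alpha_half &
      sqrt(co$x^2 + co$y^2) <= p$vein_radius_mm + p$wall_mm + h
  } else {
    ex <- p$extent_mm
    if (band_length_mm > ex[1] || band_width_mm > ex[2])
      stop("band does not fit on the slab")
    mask <- myo &
      abs(co$x - ex[1] / 2) <= band_length_mm / 2 &
      abs(co$y - ex[2] / 2) <= band_width_mm / 2
  }
  if (!any(mask)) stop("empty target band")
  structure(list(mask = mask, idx = which(mask),
                 nominal_dims_mm = c(band_width_mm, band_length_mm, p$wall_mm),
                 volume_mm3 = sum(mask) * h^3),
            class = "target_region")
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> %g x %g mm band, %d voxels, %.1f mm^3\n",
              x$nominal_dims_mm[2], x$nominal_dims_mm[1],
              length(x$idx), x$volume_mm3))
  invisible(x)
}

#' Default tissue conductivity table
#'
#' Baseline conductivities (S/m) from standard tissue-property compilations:
#' blood 0.70, myocardium 0.20, connective/background 0.10, balloon
#' insulator 1e-5 (near-zero floor).  Myocardium carries the sigmoid
#' field-dependent model by default (fold change `A`, midpoint `E_mid` V/cm,
#' width `k` V/cm); blood and background are linear.  Only conductivity
#' ratios drive the catheter comparison, and every value can be overridden.
#'
#' @param myocardium_A signed saturation fold change of myocardial
#'   conductivity under electroporation; set to 0 for a fully linear table.
#' @param E_mid,k sigmoid midpoint and width, V/cm.
#' @return named list of per-class entries (`sigma0`, optional `nonlinear`).
#' @export
default_conductivity_table <- function(myocardium_A = 2, E_mid = 500, k = 80) {
  tab <- list(
    blood = list(sigma0 = 0.70),
    myocardium = list(sigma0 = 0.20),
    connective_background = list(sigma0 = 0.10),
    balloon_insulator = list(sigma0 = 1e-5)
  )
  if (myocardium_A != 0)
    tab$myocardium$nonlinear <- list(A = myocardium_A, E_mid = E_mid, k = k)
  tab
}

#' Assign conductivities to a phantom
#'
#' @param grid an `anatomy_grid` (with any balloon insulator voxels already
#'   relabeled, see [apply_insulators()]).
#' @param table conductivity table, as [default_conductivity_table()].
#' @return object of class `conductivity_field`: per-voxel `sigma0` map plus
#'   the per-tissue nonlinearity parameters.
#' @export
assign_conductivity <- function(grid, table = default_conductivity_table()) {
  present <- sort(unique(as.vector(grid$labels)))
  present_names <- names(grid$label_names)[match(present, grid$label_names)]
  missing <- setdiff(present_names, names(table))
  if (length(missing))
    stop("conductivity table is missing entries for: ",
         paste(missing, collapse = ", "))
  bad <- vapply(table, function(e) !is.numeric(e$sigma0) || e$sigma0 < 0,
                logical(1))
  if (any(bad)) stop("all sigma0 values must be non-negative")

  lut <- numeric(max(grid$label_names))
  for (nm in names(table)) {
    if (!nm %in% names(grid$label_names)) next
    lut[grid$label_names[[nm]]] <- max(table[[nm]]$sigma0, 1e-5)
  }
  sigma0 <- array(lut[grid$labels], dim(grid$labels))
  structure(list(grid = grid, sigma0 = sigma0, table = table),
            class = "conductivity_field")
}

has_nonlinear <- function(cond) {
  any(vapply(cond$table, function(e)
    !is.null(e$nonlinear) && e$nonlinear$A != 0, logical(1)))
}

# Per-voxel conductivity map; with a field map E (V/cm) the per-tissue
# sigmoid response is applied.
sigma_map <- function(cond, E = NULL) {
  s <- cond$sigma0
  if (is.null(E)) return(s)
  for (nm in names(cond$table)) {
    nl <- cond$table[[nm]]$nonlinear
    if (is.null(nl) || nl$A == 0) next
    if (!nm %in% names(cond$grid$label_names)) next
    idx <- which(cond$grid$labels == cond$grid$label_names[[nm]])
    if (!length(idx)) next
    model <- nonlinear_conductivity(cond$table[[nm]]$sigma0, nl$A, nl$E_mid, nl$k)
    s[idx] <- sigma_of_E(model, E[idx])
  }
  s
}

#' Read / write a conductivity table as YAML
#'
#' @param path file path.
#' @return for `read_conductivity_table`, the table list.
#' @export
read_conductivity_table <- function(path) yaml::read_yaml(path)

#' @rdname read_conductivity_table
#' @param table conductivity table to write.
#' @export
write_conductivity_table <- function(table, path) {
  yaml::write_yaml(table, path)
  invisible(path)
}
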