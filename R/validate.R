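# Closed-form validation cases for the finite-volume solver.  These do not
# depend on the phantom or catheter modules: conductivity arrays and
# Dirichlet sets are built directly.

#' Parallel-plate uniform-field validation
#'
#' Uniform conductivity between full-face plate electrodes on opposite z
#' faces: the interior field must be V/d exactly (d = plate center-to-center
#' separation) and the plate current sigma * A * V / d.
#'
#' @param spacing_mm voxel spacing, mm.
#' @param extent_mm domain extent, mm (3-vector).
#' @param sigma conductivity, S/m.
#' @param V applied plate-to-plate voltage.
#' @param opts solver options.
#' @return list with `max_rel_err_E` (interior field vs V/d),
#'   `rel_err_current` (plate current vs Ohm's law), `rel_err_power`
#'   (Joule power vs I*V), `current_balance` (net Dirichlet current over
#'   drive current).
#' @export
validate_parallel_plate <- function(spacing_mm = 0.5,
                                    extent_mm = c(10, 10, 10),
                                    sigma = 0.2, V = 100,
                                    opts = solver_options(linear_tolerance = 1e-12)) {
  h <- spacing_mm / 1000
  dims <- as.integer(round(extent_mm / spacing_mm))
  sig <- array(sigma, dims)
  n <- prod(dims)
  iz <- slice.index(sig, 3)
  bottom <- which(iz == 1L)
  top <- which(iz == dims[3])
  fixed <- c(bottom, top)
  vals <- c(rep(-V / 2, length(bottom)), rep(V / 2, length(top)))
  s <- solve_poisson(sig, h, fixed, vals, opts)

  d_m <- (dims[3] - 1) * h                 # plate center separation
  e_exact <- V / d_m / 100                 # V/cm
  emag <- field_magnitude(s$phi, h)
  interior <- which(iz > 1L & iz < dims[3])
  max_rel_err_e <- max(abs(emag[interior] - e_exact) / e_exact)

  f <- net_flux(s$phi, s$g)
  i_top <- sum(f[top])
  a_m2 <- dims[1] * dims[2] * h^2
  i_exact <- sigma * a_m2 * V / d_m
  sol <- structure(list(phi = s$phi, sigma = sig, h_m = h), class = "field_solution")
  p_joule <- sum(joule_power_map(sol))
  balance <- abs(sum(f[fixed])) / abs(i_top)
  list(max_rel_err_E = max_rel_err_e,
       rel_err_current = abs(i_top - i_exact) / i_exact,
       rel_err_power = abs(p_joule - i_top * V) / (i_top * V),
       current_balance = balance,
       iterations = s$iterations)
}

#' Spherical-electrode spreading-resistance validation
#'
#' A voxelized spherical electrode of radius `a` at the center of a uniform
#' medium bounded by a grounded spherical shell of radius `b`.  The access
#' resistance is compared with the infinite-medium spreading resistance
#' `1/(4 pi sigma a)` (the `b -> inf` limit) and with the exact
#' concentric-shell closed form `(1/a - 1/b)/(4 pi sigma)`; the latter is
#' the reference for grid-convergence checks since it removes the fixed
#' domain-truncation term.
#'
#' @param spacing_mm voxel spacing, mm.
#' @param a_mm electrode radius, mm.
#' @param b_mm grounded shell radius, mm (must fit inside the domain).
#' @param extent_mm cubic domain edge, mm.
#' @param sigma conductivity, S/m.
#' @param opts solver options.
#' @return list with `R_num` (ohm), `R_inf`, `R_shell`, and signed relative
#'   errors `rel_err_inf`, `rel_err_shell`.
#' @export
validate_spreading_resistance <- function(spacing_mm = 0.5, a_mm = 3,
                                          b_mm = 16, extent_mm = 34,
                                          sigma = 0.2,
                                          opts = solver_options()) {
  stopifnot(a_mm > 2 * spacing_mm, b_mm <= extent_mm / 2)
  h <- spacing_mm / 1000
  nd <- as.integer(round(extent_mm / spacing_mm))
  dims <- c(nd, nd, nd)
  sig <- array(sigma, dims)
  co <- grid_coordinates(dims, spacing_mm, rep(-extent_mm / 2, 3))
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  inner <- which(r <= a_mm)
  shell <- which(r >= b_mm)
  fixed <- c(inner, shell)
  vals <- c(rep(1, length(inner)), rep(0, length(shell)))
  s <- solve_poisson(sig, h, fixed, vals, opts)
  f <- net_flux(s$phi, s$g)
  i <- sum(f[inner])
  r_num <- 1 / i
  r_inf <- 1 / (4 * pi * sigma * (a_mm / 1000))
  r_shell <- (1 / (a_mm / 1000) - 1 / (b_mm / 1000)) / (4 * pi * sigma)
  list(R_num = r_num, R_inf = r_inf, R_shell = r_shell,
       rel_err_inf = (r_num - r_inf) / r_inf,
       rel_err_shell = (r_num - r_shell) / r_shell,
       iterations = s$iterations)
}

#' Conservation validation on a bipolar slab case
#'
#' Two flat electrodes on the blood side of the slab phantom, driven
#' bipolar: checks net Dirichlet current balance and the identity between
#' total Joule power and the sum of electrode current x voltage.
#'
#' @param spacing_mm voxel spacing, mm.
#' @param per_vector_current amperes.
#' @param nonlinear use the field-dependent myocardium model.
#' @param opts solver options.
#' @return list with `current_balance`, `rel_err_power`, and the
#'   `field_solution`.
#' @export
validate_conservation <- function(spacing_mm = 0.5, per_vector_current = 5,
                                  nonlinear = FALSE,
                                  opts = solver_options()) {
  grid <- build_phantom("slab", list(extent_mm = c(40, 40, 20)), spacing_mm)
  target <- define_target(grid, 20, 6)
  es <- build_catheter("flex_splines", grid, target,
                       list(n_splines = 1L, electrodes_per_spline = 3L))
  cond <- assign_conductivity(grid, default_conductivity_table(
    myocardium_A = if (nonlinear) 2 else 0))
  scheme <- make_vector_scheme("flex_splines", es)
  dv <- scheme$deliveries[[1]]
  sol <- solve_delivery(cond, es, dv, per_vector_current, opts,
                        nonlinear = nonlinear)
  g <- face_conductance(sol$sigma, sol$h_m)
  f <- net_flux(sol$phi, g)
  i_pos <- sum(f[sol$pos_idx]); i_neg <- sum(f[sol$neg_idx])
  balance <- abs(i_pos + i_neg) / abs(i_pos)
  p_joule <- total_power(sol)
  p_iv <- sum(f[sol$pos_idx]) * sol$applied_voltage / 2 -
    sum(f[sol$neg_idx]) * sol$applied_voltage / 2
  list(current_balance = balance,
       rel_err_power = abs(p_joule - p_iv) / p_iv,
       sol = sol)
}

#' Run the closed-form solver validation suite
#'
#' @param spacing_mm voxel spacing for all cases, mm.
#' @return data.frame of case names, measured errors and pass criteria.
#' @export
validate_solver <- function(spacing_mm = 0.5) {
  pp <- validate_parallel_plate(spacing_mm)
  sr <- validate_spreading_resistance(spacing_mm, a_mm = 3, b_mm = 24,
                                      extent_mm = 50)
  cons <- validate_conservation(spacing_mm)
  data.frame(
    case = c("parallel_plate_field", "spreading_resistance",
             "power_conservation", "current_balance"),
    value = c(pp$max_rel_err_E, abs(sr$rel_err_inf), cons$rel_err_power,
              cons$current_balance),
    bound = c(1e-6, 0.10, 0.02, 0.01))
}
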