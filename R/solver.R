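# Finite-volume electro-quasistatic solver on the uniform voxel grid.
#
# The continuum problem is div(sigma grad phi) = 0 with Dirichlet values on
# electrode voxels and zero normal current on the outer boundary.  Voxel
# centers carry the unknown potential; faces carry conductances
# g = h * harmonic_mean(sigma_i, sigma_j)  [S], which makes the scheme
# conservative across material boundaries.

#' Solver options
#'
#' Numerical controls for the linear (PCG), nonlinear (Picard) and
#' current-control (secant) loops.
#'
#' @param linear_tolerance relative residual for the conjugate-gradient solve.
#' @param picard_tolerance maximum relative conductivity change between
#'   successive Picard iterates at convergence.
#' @param max_picard_iters Picard iteration cap.
#' @param current_tolerance relative tolerance on the achieved vs prescribed
#'   delivery current.
#' @param relaxation under-relaxation factor in (0, 1] applied to the
#'   conductivity update.
#' @param max_linear_iters conjugate-gradient iteration cap.
#' @return object of class `solver_options`.
#' @export
solver_options <- function(linear_tolerance = 1e-8, picard_tolerance = 5e-3,
                           max_picard_iters = 50L, current_tolerance = 1e-3,
                           relaxation = 0.7, max_linear_iters = 100000L) {
  stopifnot(linear_tolerance > 0, picard_tolerance > 0, current_tolerance > 0,
            relaxation > 0, relaxation <= 1,
            max_picard_iters >= 1, max_linear_iters >= 1)
  structure(list(linear_tolerance = linear_tolerance,
                 picard_tolerance = picard_tolerance,
                 max_picard_iters = as.integer(max_picard_iters),
                 current_tolerance = current_tolerance,
                 relaxation = relaxation,
                 max_linear_iters = as.integer(max_linear_iters)),
            class = "solver_options")
}

# Face conductances [S] from a voxel conductivity array [S/m] and spacing [m].
face_conductance <- function(sigma, h_m) {
  d <- dim(sigma)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  hmean <- function(a, b) {
    g <- 2 * a * b / (a + b)
    g[!is.finite(g)] <- 0
    g
  }
  list(gx = h_m * hmean(sigma[-nx, , , drop = FALSE], sigma[-1, , , drop = FALSE]),
       gy = h_m * hmean(sigma[, -ny, , drop = FALSE], sigma[, -1, , drop = FALSE]),
       gz = h_m * hmean(sigma[, , -nz, drop = FALSE], sigma[, , -1, drop = FALSE]))
}

stencil_diagonal <- function(g, d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  dg <- array(0, d)
  dg[-nx, , ] <- dg[-nx, , ] + g$gx
  dg[-1, , ]  <- dg[-1, , ]  + g$gx
  dg[, -ny, ] <- dg[, -ny, ] + g$gy
  dg[, -1, ]  <- dg[, -1, ]  + g$gy
  dg[, , -nz] <- dg[, , -nz] + g$gz
  dg[, , -1]  <- dg[, , -1]  + g$gz
  dg
}

# Right-hand side from Dirichlet values: b_i = sum_j g_ij v_j over fixed
# neighbours j of free voxel i.  Free voxels carry v = 0 so a plain shifted
# product collects exactly the fixed-neighbour terms.
dirichlet_rhs <- function(g, d, fixed_idx, values) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  v <- array(0, d)
  v[fixed_idx] <- values
  b <- array(0, d)
  b[-nx, , ] <- b[-nx, , ] + g$gx * v[-1, , ]
  b[-1, , ]  <- b[-1, , ]  + g$gx * v[-nx, , ]
  b[, -ny, ] <- b[, -ny, ] + g$gy * v[, -1, ]
  b[, -1, ]  <- b[, -1, ]  + g$gy * v[, -ny, ]
  b[, , -nz] <- b[, , -nz] + g$gz * v[, , -1]
  b[, , -1]  <- b[, , -1]  + g$gz * v[, , -nz]
  b[fixed_idx] <- 0
  b
}

# One linear solve: returns phi with Dirichlet values re-inserted.
solve_poisson <- function(sigma, h_m, fixed_idx, values, opts,
                          x0 = NULL, g = NULL) {
  d <- dim(sigma)
  n <- prod(d)
  if (length(fixed_idx) == 0L) stop("no Dirichlet voxels: singular system")
  if (is.null(g)) g <- face_conductance(sigma, h_m)
  dg <- stencil_diagonal(g, d)
  fx <- integer(n)
  fx[fixed_idx] <- 1L
  b <- dirichlet_rhs(g, d, fixed_idx, values)
  if (is.null(x0)) x0 <- numeric(n) else x0[fixed_idx] <- 0
  res <- pcg_stencil(as.integer(d), g$gx, g$gy, g$gz, dg, fx, as.numeric(b),
                     as.numeric(x0), opts$linear_tolerance,
                     opts$max_linear_iters)
  if (res$relres > opts$linear_tolerance * 10)
    stop(sprintf("linear solve did not converge: relres %.3e after %d iterations",
                 res$relres, res$iterations))
  phi <- array(res$x, d)
  phi[fixed_idx] <- values
  list(phi = phi, iterations = res$iterations, relres = res$relres, g = g)
}

# Net flux divergence F_i = sum_j g_ij (phi_i - phi_j) [A]; ~0 at converged
# free voxels, equals the injected current at Dirichlet voxels.
net_flux <- function(phi, g) {
  d <- dim(phi)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  f <- array(0, d)
  dx <- g$gx * (phi[-nx, , , drop = FALSE] - phi[-1, , , drop = FALSE])
  f[-nx, , ] <- f[-nx, , ] + dx
  f[-1, , ]  <- f[-1, , ]  - dx
  dy <- g$gy * (phi[, -ny, , drop = FALSE] - phi[, -1, , drop = FALSE])
  f[, -ny, ] <- f[, -ny, ] + dy
  f[, -1, ]  <- f[, -1, ]  - dy
  dz <- g$gz * (phi[, , -nz, drop = FALSE] - phi[, , -1, drop = FALSE])
  f[, , -nz] <- f[, , -nz] + dz
  f[, , -1]  <- f[, , -1]  - dz
  f
}

# Electric field magnitude [V/cm] by central differences (one-sided at the
# domain boundary); phi in volts, h in metres.
field_magnitude <- function(phi, h_m) {
  d <- dim(phi)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  comp <- function(along) {
    n <- d[along]
    e <- array(0, d)
    idx <- function(i) switch(along,
                              phi[i, , , drop = FALSE],
                              phi[, i, , drop = FALSE],
                              phi[, , i, drop = FALSE])
    assign_slice <- function(e, i, val) {
      switch(along,
             e[i, , ] <- val,
             e[, i, ] <- val,
             e[, , i] <- val)
      e
    }
    e <- assign_slice(e, 2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h_m))
    e <- assign_slice(e, 1, (idx(2) - idx(1)) / h_m)
    e <- assign_slice(e, n, (idx(n) - idx(n - 1)) / h_m)
    e
  }
  ex <- comp(1); ey <- comp(2); ez <- comp(3)
  sqrt(ex^2 + ey^2 + ez^2) / 100
}

#' Joule power density map
#'
#' Discrete per-voxel Joule power: each face dissipates
#' \eqn{g_{ij}(\phi_i-\phi_j)^2} watts, split half-and-half between its two
#' voxels.  Summing the map over any voxel partition is additive and the
#' total equals the delivered electrical power exactly (up to the linear
#' residual), which underpins the power-fraction metric.
#'
#' @param sol a `field_solution`.
#' @return numeric array of watts per voxel.
#' @export
joule_power_map <- function(sol) {
  g <- face_conductance(sol$sigma, sol$h_m)
  phi <- sol$phi
  d <- dim(phi)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  p <- array(0, d)
  px <- g$gx * (phi[-nx, , , drop = FALSE] - phi[-1, , , drop = FALSE])^2
  p[-nx, , ] <- p[-nx, , ] + px / 2
  p[-1, , ]  <- p[-1, , ]  + px / 2
  py <- g$gy * (phi[, -ny, , drop = FALSE] - phi[, -1, , drop = FALSE])^2
  p[, -ny, ] <- p[, -ny, ] + py / 2
  p[, -1, ]  <- p[, -1, ]  + py / 2
  pz <- g$gz * (phi[, , -nz, drop = FALSE] - phi[, , -1, drop = FALSE])^2
  p[, , -nz] <- p[, , -nz] + pz / 2
  p[, , -1]  <- p[, , -1]  + pz / 2
  p
}

#' Current through an electrode
#'
#' Discrete flux integral of current density over the voxel faces
#' surrounding the named electrode (faces internal to the electrode carry no
#' potential difference and contribute nothing).
#'
#' @param sol a `field_solution`.
#' @param electrodes the `electrode_set` used for the solve.
#' @param name electrode name, or `"patch"` for the return patch.
#' @return signed current in amperes (positive = current leaves the electrode).
#' @export
compute_current <- function(sol, electrodes, name) {
  idx <- electrode_indices(electrodes, name)
  f <- net_flux(sol$phi, face_conductance(sol$sigma, sol$h_m))
  sum(f[idx])
}

#' Field-dependent conductivity
#'
#' Monotone sigmoid electroporation model
#' \eqn{\sigma(E) = \sigma_0 (1 + A / (1 + e^{-(E - E_{mid})/k}))}:
#' \eqn{\sigma(0) \approx \sigma_0} and \eqn{\sigma(\infty) = \sigma_0(1+A)}.
#' A signed fold change `A` is supported; the default tissue table uses an
#' increase (A > 0), the standard electroporation response.
#'
#' @param model a `nonlinear_conductivity` model (see
#'   [nonlinear_conductivity()]).
#' @param E field magnitude(s), V/cm; must be non-negative.
#' @return conductivity in S/m.
#' @export
sigma_of_E <- function(model, E) {
  if (any(E < 0)) stop("negative field magnitude")
  model$sigma0 * sigmoid_factor(model, E)
}

sigmoid_factor <- function(model, E) {
  1 + model$A / (1 + exp(-(E - model$E_mid) / model$k))
}

#' Nonlinear conductivity model
#'
#' @param sigma0 zero-field conductivity, S/m.
#' @param A fold change at saturation (signed, dimensionless); `A = 0`
#'   recovers a linear tissue.
#' @param E_mid sigmoid midpoint, V/cm.
#' @param k sigmoid width, V/cm.
#' @return object of class `nonlinear_conductivity`.
#' @export
nonlinear_conductivity <- function(sigma0 = 0.2, A = 2, E_mid = 500, k = 80) {
  stopifnot(sigma0 > 0, k > 0, E_mid >= 0, A > -1)
  structure(list(sigma0 = sigma0, A = A, E_mid = E_mid, k = k),
            class = "nonlinear_conductivity")
}

# Dirichlet index/value vectors for one delivery at voltage difference V
# (positives at +V/2, negatives at -V/2).
delivery_dirichlet <- function(electrodes, delivery, V) {
  pol <- delivery$polarity
  pos <- names(pol)[pol > 0]
  neg <- names(pol)[pol < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("delivery must have at least one positive and one negative electrode")
  pos_idx <- unlist(lapply(pos, electrode_indices, electrodes = electrodes))
  neg_idx <- unlist(lapply(neg, electrode_indices, electrodes = electrodes))
  list(idx = c(pos_idx, neg_idx),
       values = c(rep(V / 2, length(pos_idx)), rep(-V / 2, length(neg_idx))),
       pos_idx = pos_idx, neg_idx = neg_idx, n_pos = length(pos))
}

#' Solve one energy delivery
#'
#' Solves the static volume-conductor problem for one delivery of a vectoring
#' scheme, driven to a prescribed per-vector current (current through each
#' positive electrode; the total drive current is `per-vector current x
#' number of positive electrodes`).  Linear runs are solved once at unit
#' voltage and scaled exactly; field-dependent conductivity is handled by
#' under-relaxed Picard iteration inside a secant loop on the applied
#' voltage.
#'
#' @param cond a `conductivity_field` from [assign_conductivity()].
#' @param electrodes an `electrode_set` from [build_catheter()].
#' @param delivery one delivery of a `vector_scheme` (electrode -> polarity
#'   map).
#' @param target_current prescribed per-vector current, amperes (> 0).
#' @param opts [solver_options()].
#' @param nonlinear logical; `FALSE` forces the linear path even if the
#'   tissue table declares field dependence.
#' @return object of class `field_solution` with elements `phi` (V),
#'   `E_mag` (V/cm), `sigma` (S/m, converged), `applied_voltage`,
#'   `achieved_current` (total), `per_vector_current`, `iterations` (Picard),
#'   `linear_iters`, `residual`.
#' @export
solve_delivery <- function(cond, electrodes, delivery, target_current,
                           opts = solver_options(), nonlinear = TRUE) {
  stopifnot(target_current > 0)
  grid <- cond$grid
  h_m <- grid$spacing_mm / 1000
  dir1 <- delivery_dirichlet(electrodes, delivery, 1)
  target_total <- target_current * dir1$n_pos
  nl <- nonlinear && has_nonlinear(cond)

  sigma0 <- sigma_map(cond)
  lin <- solve_poisson(sigma0, h_m, dir1$idx, dir1$values, opts)
  f0 <- net_flux(lin$phi, lin$g)
  i_unit <- sum(f0[dir1$pos_idx])
  if (!is.finite(i_unit) || i_unit <= 0)
    stop("degenerate delivery: no conductive path between electrodes")

  if (!nl) {
    v <- target_total / i_unit
    phi <- lin$phi * v
    sol <- list(phi = phi,
                E_mag = field_magnitude(phi, h_m),
                sigma = sigma0,
                applied_voltage = v,
                achieved_current = i_unit * v,
                per_vector_current = i_unit * v / dir1$n_pos,
                n_pos = dir1$n_pos,
                iterations = 1L,
                linear_iters = lin$iterations,
                residual = lin$relres,
                h_m = h_m, spacing_mm = grid$spacing_mm,
                delivery = delivery, pos_idx = dir1$pos_idx,
                neg_idx = dir1$neg_idx, nonlinear = FALSE)
    class(sol) <- "field_solution"
    return(sol)
  }

  # Nonlinear: Picard at fixed voltage, secant on voltage for the current.
  picard_state <- list(sigma = sigma0, phi = NULL)
  picard_solve <- function(V) {
    dirv <- delivery_dirichlet(electrodes, delivery, V)
    sigma <- picard_state$sigma
    phi <- if (is.null(picard_state$phi)) lin$phi * V else picard_state$phi
    history <- numeric(0)
    it <- 0L
    lin_iters <- 0L
    relres <- NA_real_
    g <- NULL
    repeat {
      s <- solve_poisson(sigma, h_m, dirv$idx, dirv$values, opts,
                         x0 = as.numeric(phi))
      phi <- s$phi; g <- s$g
      lin_iters <- lin_iters + s$iterations
      relres <- s$relres
      e <- field_magnitude(phi, h_m)
      s_new <- sigma_map(cond, e)
      s_rel <- (1 - opts$relaxation) * sigma + opts$relaxation * s_new
      delta <- max(abs(s_rel - sigma) / pmax(sigma, 1e-12))
      history <- c(history, delta)
      sigma <- s_rel
      it <- it + 1L
      if (delta < opts$picard_tolerance) break
      if (it >= opts$max_picard_iters)
        stop(sprintf(paste0("Picard iteration did not converge in %d steps; ",
                            "relative sigma-change history: %s"),
                     it, paste(signif(history, 3), collapse = " ")))
    }
    picard_state$sigma <<- sigma
    picard_state$phi <<- as.numeric(phi)
    f <- net_flux(phi, g)
    list(phi = phi, sigma = sigma, E = field_magnitude(phi, h_m),
         current = sum(f[dirv$pos_idx]), iterations = it,
         linear_iters = lin_iters, relres = relres, history = history)
  }

  v0 <- target_total / i_unit          # linear estimate
  s0 <- picard_solve(v0)
  v1 <- v0 * target_total / s0$current # one Ohmic correction
  sol_v <- s0; v_prev <- v0; i_prev <- s0$current
  v_cur <- v1
  total_picard <- s0$iterations
  total_lin <- s0$linear_iters
  for (k in seq_len(30L)) {
    if (abs(i_prev - target_total) / target_total < opts$current_tolerance) {
      v_cur <- v_prev
      break
    }
    s1 <- picard_solve(v_cur)
    total_picard <- total_picard + s1$iterations
    total_lin <- total_lin + s1$linear_iters
    if (abs(s1$current - target_total) / target_total < opts$current_tolerance) {
      sol_v <- s1
      break
    }
    dv <- (v_cur - v_prev) / (s1$current - i_prev)
    v_new <- v_cur + (target_total - s1$current) * dv
    if (!is.finite(v_new) || v_new <= 0) v_new <- v_cur * target_total / s1$current
    v_prev <- v_cur; i_prev <- s1$current
    v_cur <- v_new
    sol_v <- s1
    if (k == 30L)
      stop("secant iteration on applied voltage did not converge")
  }

  sol <- list(phi = sol_v$phi,
              E_mag = sol_v$E,
              sigma = sol_v$sigma,
              applied_voltage = v_cur,
              achieved_current = sol_v$current,
              per_vector_current = sol_v$current / dir1$n_pos,
              n_pos = dir1$n_pos,
              iterations = total_picard,
              linear_iters = total_lin,
              residual = sol_v$relres,
              picard_history = sol_v$history,
              h_m = h_m, spacing_mm = grid$spacing_mm,
              delivery = delivery, pos_idx = dir1$pos_idx,
              neg_idx = dir1$neg_idx, nonlinear = TRUE)
  class(sol) <- "field_solution"
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(paste0("<field_solution> %s delivery: %.1f V applied, ",
                     "%.3f A achieved (%.3f A per vector), %d Picard / %d CG ",
                     "iterations, residual %.2e\n"),
              x$delivery$name %||% "unnamed", x$applied_voltage,
              x$achieved_current, x$per_vector_current,
              x$iterations, x$linear_iters, x$residual))
  invisible(x)
}

#' Current density magnitude map
#'
#' @param sol a `field_solution`.
#' @return array of |J| in A/cm^2 (sigma * |E|).
#' @export
current_density_map <- function(sol) {
  sol$sigma * sol$E_mag * 100 / 1e4  # (S/m * V/m) = A/m^2 -> A/cm^2
}

#' Total Joule power of a solution
#'
#' @param sol a `field_solution`.
#' @return watts.
#' @export
total_power <- function(sol) sum(joule_power_map(sol))
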