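# Outcome metrics: transmural fraction, per-vector current for 90%
# transmurality, percent power into target, electrode current density and
# dose-duration arithmetic.

#' Maximum field over deliveries
#'
#' Sequential deliveries combine by the union rule: the lesion at a voxel is
#' driven by the maximum field magnitude it sees across deliveries.
#'
#' @param solutions list of `field_solution`s (or of E-magnitude arrays).
#' @return array of per-voxel maximum |E| in V/cm.
#' @export
max_field <- function(solutions) {
  emax <- NULL
  for (s in solutions) {
    e <- if (inherits(s, "field_solution")) s$E_mag else s
    emax <- if (is.null(emax)) e else pmax(emax, e)
  }
  if (is.null(emax)) stop("no solutions supplied")
  emax
}

#' Transmural fraction of the target
#'
#' Fraction of target voxels whose maximum field magnitude across the
#' supplied deliveries exceeds the electroporation threshold (default
#' 600 V/cm, a conservative lethal-field threshold for myocardium).
#'
#' @param solutions list of `field_solution`s or E-magnitude arrays sharing
#'   the target's grid.
#' @param target a `target_region`.
#' @param threshold V/cm.
#' @return fraction in \[0, 1\].
#' @export
transmural_fraction <- function(solutions, target, threshold = 600) {
  if (!length(target$idx)) stop("empty target")
  emax <- max_field(solutions)
  mean(emax[target$idx] > threshold)
}

#' Lesion volume
#'
#' Volume of myocardium (anywhere in the phantom) above the field threshold.
#'
#' @param solutions list of `field_solution`s or E arrays.
#' @param grid the `anatomy_grid`.
#' @param threshold V/cm.
#' @return volume in mm^3.
#' @export
lesion_volume <- function(solutions, grid, threshold = 600) {
  emax <- max_field(solutions)
  myo <- label_mask_idx(grid, "myocardium")
  sum(emax[myo] > threshold) * grid$spacing_mm^3
}

# Closed-form per-vector current for a linear case: the smallest current at
# which the level-quantile target voxel reaches the threshold, by exact
# scaling of the reference solve.
transmurality_current_closed_form <- function(emax_ref, target, i_ref,
                                              level = 0.9, threshold = 600) {
  e <- sort(emax_ref[target$idx], decreasing = TRUE)
  k <- ceiling(level * length(e))
  i_ref * threshold / e[k]
}

#' Per-vector current for transmurality
#'
#' Smallest per-vector current within the search range at which the
#' transmural fraction of the target reaches `level`, found by bisection to
#' 1\% relative width.  All counted deliveries are driven at the same
#' per-vector current.  With linear conductivity the reference solves are
#' scaled exactly, so the bisection reuses one solve per delivery; with
#' field-dependent conductivity every probe re-solves the deliveries.
#'
#' @param case list with elements `cond` (`conductivity_field`), `electrodes`
#'   (`electrode_set`), `scheme` (`vector_scheme`), `target`
#'   (`target_region`), optional `grid`, `opts`, `nonlinear`, `i_ref`.
#' @param level required transmural fraction in (0, 1\].
#' @param search_range_A per-vector current search interval, amperes.
#' @param rel_tol relative bisection width at termination.
#' @param solutions optional precomputed reference `field_solution`s for the
#'   counted deliveries (linear path only).
#' @return list with `current` (A), `achieved` (logical; `FALSE` means the
#'   level is not reached at the search maximum, reported rather than
#'   thrown), `fraction` at the returned current, `note`.
#' @export
current_for_transmurality <- function(case, level = 0.9,
                                      search_range_A = c(2, 70),
                                      rel_tol = 0.01, solutions = NULL) {
  stopifnot(level > 0, level <= 1, search_range_A[1] > 0,
            search_range_A[2] > search_range_A[1])
  opts <- case$opts %||% solver_options()
  nonlinear <- (case$nonlinear %||% TRUE) && has_nonlinear(case$cond)
  counted <- Filter(function(d) isTRUE(d$counted), case$scheme$deliveries)
  if (!length(counted)) stop("scheme has no counted deliveries")
  threshold <- case$threshold %||% 600

  if (!nonlinear) {
    i_ref <- case$i_ref %||% 10
    if (is.null(solutions))
      solutions <- solve_counted_deliveries(case, i_ref, opts,
                                            nonlinear = FALSE)
    emax <- max_field(solutions)
    frac_at <- function(i) {
      mean(emax[case$target$idx] * (i / i_ref) > threshold)
    }
  } else {
    frac_at <- function(i) {
      sols <- solve_counted_deliveries(case, i, opts, nonlinear = TRUE)
      transmural_fraction(sols, case$target, threshold)
    }
  }

  lo <- search_range_A[1]; hi <- search_range_A[2]
  f_hi <- frac_at(hi)
  if (f_hi < level)
    return(list(current = NA_real_, achieved = FALSE, fraction = f_hi,
                note = sprintf("not achieved at %g A", hi)))
  f_lo <- frac_at(lo)
  if (f_lo >= level)
    return(list(current = lo, achieved = TRUE, fraction = f_lo,
                note = "achieved at the search minimum"))
  while ((hi - lo) / hi > rel_tol) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) >= level) hi <- mid else lo <- mid
  }
  list(current = hi, achieved = TRUE, fraction = frac_at(hi), note = "bisection")
}

# Solve every counted delivery of a case at the given per-vector current.
solve_counted_deliveries <- function(case, per_vector_current, opts = NULL,
                                     nonlinear = TRUE) {
  opts <- opts %||% case$opts %||% solver_options()
  counted <- Filter(function(d) isTRUE(d$counted), case$scheme$deliveries)
  lapply(counted, function(dv) {
    es <- electrodes_for_delivery(case$electrodes, case$grid %||%
                                    case$cond$grid, case$target, dv)
    cond <- case$cond
    solve_delivery(cond, es, dv, per_vector_current, opts,
                   nonlinear = nonlinear)
  })
}

#' Percent of delivered power reaching the target
#'
#' Joule power dissipated inside the target as a percentage of the total
#' delivered power, accumulated over the counted deliveries:
#' `100 * sum_d P_target(d) / sum_d I(d) * V(d)` (power-summed accounting;
#' `method = "averaged"` instead averages the per-delivery percentages).
#'
#' @param solutions list of converged `field_solution`s for the counted
#'   deliveries.
#' @param target a `target_region`.
#' @param method `"summed"` (default) or `"averaged"`.
#' @return percentage in \[0, 100\].
#' @export
power_fraction_in_target <- function(solutions, target,
                                     method = c("summed", "averaged")) {
  method <- match.arg(method)
  pt <- vapply(solutions, function(s) sum(joule_power_map(s)[target$idx]),
               numeric(1))
  pd <- vapply(solutions, function(s)
    abs(s$achieved_current * s$applied_voltage), numeric(1))
  if (all(pd == 0)) stop("zero delivered power")
  if (method == "summed") 100 * sum(pt) / sum(pd) else mean(100 * pt / pd)
}

#' Electrode current density
#'
#' Per-vector current divided by the design's electrode metal area
#' (see [electrode_metal_area()] for the per-design area convention).
#'
#' @param current per-vector current, amperes.
#' @param area electrode metal area, cm^2 (> 0).
#' @return A/cm^2 (unrounded; reports round to the nearest integer).
#' @export
electrode_current_density <- function(current, area) {
  if (area <= 0) stop("electrode area must be positive")
  if (current < 0) stop("current must be non-negative")
  current / area
}

#' Total energy delivery duration
#'
#' @param schedule list or `dose_schedule` with `n_applications`,
#'   `n_deliveries_per_application` and `delivery_duration_ms`, all >= 0.
#' @return total delivery duration in milliseconds (the product).
#' @export
total_delivery_duration <- function(schedule) {
  with(schedule, {
    stopifnot(n_applications >= 0, n_deliveries_per_application >= 0,
              delivery_duration_ms >= 0)
    n_applications * n_deliveries_per_application * delivery_duration_ms
  })
}

#' Published per-PV dose schedules
#'
#' Energy-delivery schedules per pulmonary vein compiled from pivotal-study
#' protocols and live cases, used for the dose-duration arithmetic:
#' applications per PV, deliveries per application and delivery duration.
#'
#' @return data.frame with one row per design and a `total_ms` column.
#' @export
dose_schedules <- function() {
  df <- data.frame(
    design = c("oneshot_sphere", "focal_sphere_9mm", "penta_spline",
               "circular"),
    n_applications = c(4, 7, 8, 12),
    n_deliveries_per_application = c(30, 12, 5, 4),
    delivery_duration_ms = c(150, 150, 200, 130))
  df$total_ms <- df$n_applications * df$n_deliveries_per_application *
    df$delivery_duration_ms
  df
}
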