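# Shared fixtures, built once per test run.  The coarse (1 mm) antrum
# phantom resolves the 2.5 mm wall with 2-3 voxels and keeps full-pipeline
# tests in the seconds-to-minutes range; geometry-sensitive checks use the
# 0.5 mm phantom.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

antrum_coarse <- function() cached("antrum1", build_phantom("antrum", spacing_mm = 1))
antrum_half <- function() cached("antrum05", build_phantom("antrum", spacing_mm = 0.5))

target_coarse <- function() cached("target1", define_target(antrum_coarse()))

slab_half <- function() cached(
  "slab05", build_phantom("slab", list(extent_mm = c(40, 40, 16), base_mm = 3),
                          spacing_mm = 0.5))

linear_table <- function() default_conductivity_table(myocardium_A = 0)

# One-tripole flex case on the slab: the cheapest complete
# phantom+catheter+scheme+solve path.
slab_tripole_case <- function(nonlinear = FALSE) {
  key <- paste0("slabcase", nonlinear)
  cached(key, {
    grid <- slab_half()
    target <- define_target(grid, 12, 6)  # spanned by the single tripole
    es <- build_catheter("flex_splines", grid, target,
                         list(n_splines = 1L, electrodes_per_spline = 3L))
    cond <- assign_conductivity(grid, default_conductivity_table(
      myocardium_A = if (nonlinear) 2 else 0))
    scheme <- make_vector_scheme("flex_splines", es)
    list(cond = cond, electrodes = es, scheme = scheme, target = target,
         grid = grid, opts = solver_options(), nonlinear = nonlinear,
         threshold = 600, i_ref = 5)
  })
}
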