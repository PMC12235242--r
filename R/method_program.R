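#' Column description
#'
#' Physical description of the packed chromatographic column. All lengths are
#' stored in meters; `ligand_density` is the total ligand capacity of the
#' stationary phase (model units, per liter stationary phase) and
#' `plate_count` the column efficiency used to derive the apparent axial
#' dispersion coefficient.
#'
#' @param length column length (m)
#' @param inner_diameter column inner diameter (m)
#' @param total_porosity total porosity (dimensionless, in (0,1))
#' @param ligand_density ligand density Lambda (model units)
#' @param plate_count number of theoretical plates (>= 1)
#' @return an object of class `column_spec`
#' @export
column_spec <- function(length, inner_diameter, total_porosity,
                        ligand_density, plate_count) {
  stopifnot(length > 0, inner_diameter > 0,
            total_porosity > 0, total_porosity < 1,
            ligand_density > 0, plate_count >= 1)
  structure(
    list(length = length, inner_diameter = inner_diameter,
         total_porosity = total_porosity, ligand_density = ligand_density,
         plate_count = plate_count),
    class = "column_spec")
}

#' @export
print.column_spec <- function(x, ...) {
  cat(sprintf("<column_spec> L = %g mm, ID = %g mm, eps_t = %g, Lambda = %g, N = %g\n",
              x$length * 1000, x$inner_diameter * 1000, x$total_porosity,
              x$ligand_density, x$plate_count))
  invisible(x)
}

#' Adsorption parameters of one component
#'
#' Parameters of the simplified stoichiometric displacement model (SDM): the
#' characteristic charge `nu` (modifier molecules displaced per adsorbed
#' solute), equilibrium constant `keq`, steric shielding factor `sigma`, and
#' kinetic coefficient `kkin` (multiplies dq/dt, so larger values mean slower
#' adsorption kinetics).
#'
#' @param name component label, one of "W", "P", "S"
#' @param charge_nu characteristic charge (> 0)
#' @param keq equilibrium constant (>= 0, model units)
#' @param sigma shielding factor (>= 0)
#' @param kkin kinetic coefficient (> 0, model units)
#' @return an object of class `component_params`
#' @export
component_params <- function(name, charge_nu, keq, sigma, kkin) {
  stopifnot(charge_nu > 0, keq >= 0, sigma >= 0, kkin > 0)
  structure(list(name = name, charge_nu = charge_nu, keq = keq,
                 sigma = sigma, kkin = kkin),
            class = "component_params")
}

#' @export
print.component_params <- function(x, ...) {
  cat(sprintf("<component_params> %s: nu = %g, keq = %g, sigma = %g, kkin = %g\n",
              x$name, x$charge_nu, x$keq, x$sigma, x$kkin))
  invisible(x)
}

#' One step of a chromatographic method
#'
#' @param kind one of "equilibration", "load", "wash", "gradient", "strip"
#' @param percentB_start modifier level at step start (%B, 0-100)
#' @param percentB_end modifier level at step end; must equal
#'   `percentB_start` for non-gradient steps
#' @param velocity superficial velocity (m/s); use [cmh_to_ms()] for values
#'   configured in cm/h
#' @param duration_cv step duration in column volumes
#' @param feed named vector of adsorbate feed concentrations (g/L); nonzero
#'   only for load steps
#' @return an object of class `method_step`
#' @export
method_step <- function(kind, percentB_start, percentB_end = percentB_start,
                        velocity, duration_cv,
                        feed = c(W = 0, P = 0, S = 0)) {
  kind <- match.arg(kind, c("equilibration", "load", "wash", "gradient", "strip"))
  stopifnot(percentB_start >= 0, percentB_start <= 100,
            percentB_end >= 0, percentB_end <= 100,
            velocity > 0, duration_cv > 0)
  if (kind != "gradient" && percentB_start != percentB_end)
    stopf("non-gradient step '%s' must have a constant %%B", kind)
  if (kind != "load" && any(feed != 0))
    stopf("feed concentrations must be zero outside the load step")
  structure(list(kind = kind, percentB_start = percentB_start,
                 percentB_end = percentB_end, velocity = velocity,
                 duration_cv = duration_cv, feed = feed),
            class = "method_step")
}

#' Multi-step chromatographic method program
#'
#' Ordered sequence of method steps run on a given column. Step durations are
#' configured in column volumes (CV) and converted to elapsed time through the
#' per-step superficial velocity: one CV at superficial velocity u takes
#' L/u seconds (empty-column volume over volumetric flow).
#'
#' @param steps list of [method_step()] objects; must contain at least one
#'   gradient step
#' @param column a [column_spec()]
#' @return an object of class `method_program` with a precomputed time grid
#' @export
method_program <- function(steps, column) {
  stopifnot(inherits(column, "column_spec"), length(steps) >= 1)
  if (!any(vapply(steps, function(s) s$kind == "gradient", logical(1))))
    stopf("a method program must contain at least one gradient step")
  dur_s <- vapply(steps, function(s) s$duration_cv * column$length / s$velocity,
                  numeric(1))
  dur_cv <- vapply(steps, function(s) s$duration_cv, numeric(1))
  if (any(dur_s <= 0)) stopf("step durations must be strictly positive")
  structure(
    list(steps = steps, column = column,
         t_bounds = c(0, cumsum(dur_s)),       # seconds, step boundaries
         cv_bounds = c(0, cumsum(dur_cv))),    # column volumes
    class = "method_program")
}

#' @export
print.method_program <- function(x, ...) {
  cat(sprintf("<method_program> %d steps, %.1f CV, %.0f s total\n",
              length(x$steps), max(x$cv_bounds), max(x$t_bounds)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %-13s %5.1f-%5.1f %%B  %6.1f cm/h  %4.2f CV\n",
                s$kind, s$percentB_start, s$percentB_end,
                ms_to_cmh(s$velocity), s$duration_cv))
  }
  invisible(x)
}

program_span <- function(program) max(program$t_bounds)

# index of the active step at time t; boundaries belong to the later step
# except the final end point
program_step_at <- function(program, t) {
  tb <- program$t_bounds
  if (t < -1e-9 || t > tb[length(tb)] + 1e-9)
    stopf("time %g s outside the program span [0, %g]", t, tb[length(tb)])
  i <- findInterval(t, tb, rightmost.closed = TRUE)
  min(max(i, 1L), length(program$steps))
}

#' Inlet profile of a method program
#'
#' Evaluates the piecewise inlet boundary condition driving the column: the
#' modifier level (constant per step, linear ramp within gradient steps) and
#' the adsorbate feed concentrations (nonzero only during load steps).
#'
#' @param program a [method_program()]
#' @param t time (s), within the program span
#' @return list with elements `percentB` (scalar) and `feed` (named numeric
#'   vector of adsorbate concentrations, g/L)
#' @export
inlet_profile <- function(program, t) {
  i <- program_step_at(program, t)
  s <- program$steps[[i]]
  t0 <- program$t_bounds[i]; t1 <- program$t_bounds[i + 1]
  frac <- if (t1 > t0) (t - t0) / (t1 - t0) else 0
  frac <- min(max(frac, 0), 1)
  pb <- s$percentB_start + frac * (s$percentB_end - s$percentB_start)
  feed <- if (s$kind == "load") s$feed else s$feed * 0
  list(percentB = pb, feed = feed)
}

#' Apparent axial dispersion coefficient from plate count
#'
#' Lumps all band-broadening into an apparent dispersion coefficient derived
#' from column efficiency, `Dapp = u * L / (2 * eps_t * N)`. Being linear in
#' the superficial velocity `u`, it is re-evaluated whenever the method step
#' velocity changes, making dispersion flow-dependent.
#'
#' @param u superficial velocity (m/s)
#' @param column a [column_spec()]
#' @return apparent dispersion coefficient (m^2/s)
#' @export
apparent_dispersion <- function(u, column) {
  stopifnot(u > 0)
  u * column$length / (2 * column$total_porosity * column$plate_count)
}

#' Convert between column volumes and elapsed time
#'
#' Column volumes are converted to time through the per-step volumetric flow
#' (superficial velocity times cross-section over empty-column volume), summed
#' piecewise over the method steps. The two functions are exact inverses.
#'
#' @param program a [method_program()]
#' @param volume_cv cumulative volume (CV), scalar or vector
#' @param t elapsed time (s), scalar or vector
#' @return elapsed seconds (`cv_to_time`) or cumulative CV (`time_to_cv`)
#' @export
cv_to_time <- function(program, volume_cv) {
  if (any(volume_cv < 0)) stopf("volume must be nonnegative")
  if (any(volume_cv > max(program$cv_bounds) + 1e-9))
    stopf("volume beyond the program span (%g CV)", max(program$cv_bounds))
  vapply(volume_cv, function(v) {
    i <- findInterval(v, program$cv_bounds, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(program$steps))
    dv <- v - program$cv_bounds[i]
    program$t_bounds[i] + dv * program$column$length / program$steps[[i]]$velocity
  }, numeric(1))
}

#' @rdname cv_to_time
#' @export
time_to_cv <- function(program, t) {
  if (any(t < 0)) stopf("time must be nonnegative")
  if (any(t > program_span(program) + 1e-6))
    stopf("time beyond the program span (%g s)", program_span(program))
  vapply(t, function(tt) {
    i <- program_step_at(program, tt)
    dt <- tt - program$t_bounds[i]
    program$cv_bounds[i] + dt * program$steps[[i]]$velocity / program$column$length
  }, numeric(1))
}
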