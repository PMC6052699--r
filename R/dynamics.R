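#' Simulation configuration
#'
#' Time step and convergence tolerances for the quasi-static relaxation
#' discipline: every surgical action (cut, suture tightening increment,
#' forceps move) is followed by [relax()] before the state is inspected.
#'
#' @param dt integration time step, s
#' @param max_steps maximum steps per relaxation
#' @param velocity_tolerance convergence bound on max vertex speed, mm/s
#' @param displacement_tolerance convergence bound on max per-step
#'   displacement, mm
#' @param gravity 3-vector acceleration, mm/s^2 (default zero: the patch
#'   lies in its rest plane)
#' @param drag global viscous drag coefficient, 1/s: damps transverse
#'   (bending) modes that axial spring damping cannot reach; zero at rest,
#'   so equilibrium positions are unaffected
#' @param speed_ceiling divergence detector: a step whose max speed exceeds
#'   this flags the relaxation as diverged, mm/s
#' @param seed integer seed recorded with the configuration
#' @return a `sim_config` list
#' @export
sim_config <- function(dt = 0.005, max_steps = 60000,
                       velocity_tolerance = 1e-3,
                       displacement_tolerance = 1e-4,
                       gravity = c(0, 0, 0), drag = 2,
                       speed_ceiling = 1e5, seed = 1L) {
  stopifnot(dt > 0, max_steps >= 1, velocity_tolerance > 0,
            displacement_tolerance > 0, length(gravity) == 3)
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 velocity_tolerance = velocity_tolerance,
                 displacement_tolerance = displacement_tolerance,
                 gravity = as.numeric(gravity),
                 drag = drag,
                 speed_ceiling = speed_ceiling,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Force exerted by one spring on its two endpoints
#'
#' Hookean elastic force of magnitude `stiffness * |length - rest_length|`
#' directed to restore the rest length, plus axial viscous damping
#' `-damping * (relative velocity projected on the spring axis)`. The two
#' returned forces are equal and opposite. Coincident endpoints have no
#' defined axis; the force is then zero (such states are transient, e.g.
#' freshly duplicated cut vertices).
#'
#' @param rest_length,stiffness,damping spring constants
#' @param xa,xb endpoint positions (3-vectors, mm)
#' @param va,vb endpoint velocities (3-vectors, mm/s)
#' @return list with `fa` and `fb`, the forces on the two endpoints
#' @export
spring_force <- function(rest_length, stiffness, damping,
                         xa, xb, va = c(0, 0, 0), vb = c(0, 0, 0)) {
  d <- xb - xa
  len <- sqrt(sum(d^2))
  if (len < 1e-12) return(list(fa = c(0, 0, 0), fb = c(0, 0, 0)))
  dir <- d / len
  f <- stiffness * (len - rest_length) + damping * sum((vb - va) * dir)
  list(fa = f * dir, fb = -f * dir)
}

# Assemble the integrator inputs from the lattice: alive springs plus any
# active suture constraint springs; kinematic mask for fixed, tombstoned
# and grabbed vertices; active welds and rigid groups.
integration_inputs <- function(lat) {
  idx <- which(lat$s_alive)
  si <- lat$s_i[idx]; sj <- lat$s_j[idx]
  rest <- lat$s_rest[idx]; kk <- lat$s_k[idx]; cc <- lat$s_c[idx]
  for (s in lat$sutures) {
    if (!is.null(s) && s$status != "CLOSED" && isTRUE(s$spring_active)) {
      si <- c(si, s$free); sj <- c(sj, s$anchor)
      rest <- c(rest, s$rest_current); kk <- c(kk, s$stiffness)
      cc <- c(cc, s$damping)
    }
  }
  grabbed <- rep(FALSE, length(lat$alive))
  for (g in lat$grabs) if (isTRUE(g$active)) grabbed[g$vertices] <- TRUE
  invmass <- ifelse(lat$alive & !lat$fixed & !grabbed, 1 / lat$mass, 0)
  rg <- Filter(function(g) isTRUE(g$active), lat$rigid_groups)
  list(si = si, sj = sj, rest = rest, k = kk, c = cc,
       invmass = invmass,
       rigid_idx = lapply(rg, `[[`, "chain"),
       rigid_ref = lapply(rg, `[[`, "reference_shape"),
       weld_free = lat$welds[, 1], weld_anchor = lat$welds[, 2])
}

run_integrator <- function(lat, config, max_steps, check_convergence,
                           record_energy = FALSE) {
  inp <- integration_inputs(lat)
  out <- integrate_system(lat$pos, lat$vel, lat$mass, inp$invmass,
                          inp$si, inp$sj, inp$rest, inp$k, inp$c,
                          config$dt, config$gravity,
                          as.integer(max_steps),
                          config$velocity_tolerance,
                          config$displacement_tolerance,
                          inp$rigid_idx, inp$rigid_ref,
                          as.integer(inp$weld_free),
                          as.integer(inp$weld_anchor),
                          config$drag,
                          config$speed_ceiling, check_convergence,
                          record_energy)
  lat$pos <- out$pos
  lat$vel <- out$vel
  out
}

#' Advance the lattice by one semi-implicit Euler step
#'
#' Velocities are updated from the accumulated spring, damping and gravity
#' forces, then positions from the new velocities. Fixed, tombstoned and
#' grabbed vertices are kinematic and do not move; weld pairs and active
#' rigid chains are enforced by projection after the position update.
#'
#' @param lattice a `skin_lattice`
#' @param config a [sim_config()]
#' @return invisibly, a list with the step's max speed and displacement
#' @export
step <- function(lattice, config = sim_config()) {
  out <- run_integrator(lattice, config, 1L, FALSE)
  invisible(list(max_speed = out$max_speed, max_disp = out$max_disp,
                 diverged = out$diverged))
}

#' Relax the lattice to quasi-static equilibrium
#'
#' Repeatedly steps the system until the maximum vertex speed falls below
#' `velocity_tolerance` and the maximum per-step displacement below
#' `displacement_tolerance`, or `max_steps` is reached. Deterministic for
#' a given state and configuration (fixed iteration order by id).
#'
#' @inheritParams step
#' @param record_energy also return the per-step total mechanical energy
#'   trace (elastic + kinetic)
#' @return a `relax_report` list: steps_taken, converged, diverged,
#'   max_residual_velocity, max_displacement_last_step,
#'   total_elastic_energy, and optionally energy_trace
#' @export
relax <- function(lattice, config = sim_config(), record_energy = FALSE) {
  out <- run_integrator(lattice, config, config$max_steps, TRUE,
                        record_energy)
  rep <- structure(list(steps_taken = out$steps,
                        converged = out$converged,
                        diverged = out$diverged,
                        max_residual_velocity = out$max_speed,
                        max_displacement_last_step = out$max_disp,
                        total_elastic_energy = out$elastic_energy,
                        energy_trace = out$energy_trace),
                   class = "relax_report")
  rep
}

#' @export
print.relax_report <- function(x, ...) {
  cat(sprintf(
    "<relax_report> %s in %d steps | residual speed %.3g mm/s, last disp %.3g mm, elastic energy %.4g\n",
    if (x$converged) "converged" else if (x$diverged) "DIVERGED"
    else "not converged", x$steps_taken, x$max_residual_velocity,
    x$max_displacement_last_step, x$total_elastic_energy))
  invisible(x)
}

# Total elastic energy over alive springs, for metrics.
elastic_energy <- function(lat) {
  idx <- which(lat$s_alive)
  d <- lat$pos[lat$s_i[idx], , drop = FALSE] -
    lat$pos[lat$s_j[idx], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  sum(0.5 * lat$s_k[idx] * (len - lat$s_rest[idx])^2)
}

# Max/mean relative strain |length - rest| / rest over alive springs.
spring_strain_summary <- function(lat) {
  idx <- which(lat$s_alive)
  d <- lat$pos[lat$s_i[idx], , drop = FALSE] -
    lat$pos[lat$s_j[idx], , drop = FALSE]
  strain <- abs(sqrt(rowSums(d^2)) - lat$s_rest[idx]) / lat$s_rest[idx]
  c(max_strain = max(strain, 0), mean_strain = mean(strain))
}
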