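#' Linear rate or diffusion law
#'
#' Fission and fusion rates and the diffusion constant of a mitochondrial
#' network all scale linearly with the network's 3D-equivalent volume.  A
#' `rate_law` stores the slope and intercept of that least-squares line;
#' evaluation is clamped at zero because rates are physical quantities and
#' the fits extend below zero outside the observed volume range.
#'
#' @param slope Slope of the law. Units: per um^3 per s for event rates,
#'   per um per s for diffusion.
#' @param intercept Intercept. Units: per s for event rates, um^2/s for
#'   diffusion.
#' @return An object of class `rate_law`.
#' @examples
#' kfis_wt <- rate_law(1.28e-3, -1.67e-3)
#' eval_rate(kfis_wt, n_particles = 54, unit_mito_volume = 0.12)
#' @export
rate_law <- function(slope, intercept) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law> %.4g * v %+.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Evaluate a rate law for a network of particles
#'
#' The network's 3D-equivalent volume is the particle count times the unit
#' mitochondrion volume; the law is evaluated at that volume and clamped at
#' zero.
#'
#' @param law A [rate_law()].
#' @param n_particles Number of particles in the network (>= 1).
#' @param unit_mito_volume Volume of one unit mitochondrion, um^3.
#' @return Non-negative per-second rate (or um^2/s for a diffusion law).
#' @export
eval_rate <- function(law, n_particles, unit_mito_volume) {
  stopifnot(inherits(law, "rate_law"), all(n_particles >= 1),
            unit_mito_volume > 0)
  pmax(0, law$slope * (n_particles * unit_mito_volume) + law$intercept)
}

#' Per-timestep event probability from a per-second rate
#'
#' Converts a rate to the Bernoulli probability of one event in a timestep.
#' The default is the linear approximation `rate * dt` capped at 1; at the
#' calibrated rates and dt = 0.1 s the difference from `1 - exp(-rate*dt)`
#' is below 0.1%.  The exponential form is available via `exact = TRUE`.
#'
#' @param rate Non-negative per-second rate.
#' @param dt Timestep, seconds.
#' @param exact Use `1 - exp(-rate*dt)` instead of the capped linear form.
#' @return Probability in `[0, 1]`.
#' @export
per_step_probability <- function(rate, dt, exact = FALSE) {
  stopifnot(all(rate >= 0), dt > 0)
  if (exact) 1 - exp(-rate * dt) else pmin(1, rate * dt)
}

sphere_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

#' Derive the simulation geometry from the mother-cell volume
#'
#' The mother cell is treated as a sphere; mitochondria move on its inner
#' cortex, so the simulation domain is a periodic square whose area equals
#' the sphere's surface area.
#'
#' @param mother_cell_volume Mean mother (progenitor) cell volume, um^3.
#' @return List with `mother_radius` (um), `mother_surface_area` (um^2) and
#'   `box_side` (um).
#' @examples
#' derive_geometry(54.04)
#' @export
derive_geometry <- function(mother_cell_volume) {
  if (!is.numeric(mother_cell_volume) || length(mother_cell_volume) != 1L ||
      !is.finite(mother_cell_volume) || mother_cell_volume <= 0)
    stop("mother_cell_volume must be a single positive number")
  r <- sphere_radius(mother_cell_volume)
  sa <- 4 * pi * r^2
  list(mother_radius = r, mother_surface_area = sa, box_side = sqrt(sa))
}

#' Derive the particle radius from the unit mitochondrion volume
#'
#' The unit mitochondrion (calibrated to the mean fragment volume of a
#' fusion-null strain) is treated as a sphere.
#'
#' @param unit_mito_volume Volume of one unit mitochondrion, um^3.
#' @return Sphere radius, um.
#' @export
derive_particle_radius <- function(unit_mito_volume) {
  if (!is.numeric(unit_mito_volume) || length(unit_mito_volume) != 1L ||
      !is.finite(unit_mito_volume) || unit_mito_volume <= 0)
    stop("unit_mito_volume must be a single positive number")
  sphere_radius(unit_mito_volume)
}

#' Derive the particle counts of a simulation
#'
#' Total, inherited and aggregate-marked particle counts are the floors of
#' the corresponding volume ratios (the printed calibrated values all equal
#' the floor of the measured ratios).
#'
#' @param total_mito_volume Mean total mitochondrial volume per cell, um^3.
#' @param unit_mito_volume Volume of one unit mitochondrion, um^3.
#' @param bud_mito_volume Mean mitochondrial volume inherited by the bud, um^3.
#' @param dump_occupancy Fraction of mitochondrial volume occupied by DUMP,
#'   in (0, 1).
#' @return List of integers `n_total`, `n_inherit`, `n_dump`.
#' @examples
#' derive_counts(6.56, 0.12, 1.83, 0.122)  # 54, 15, 6
#' @export
derive_counts <- function(total_mito_volume, unit_mito_volume,
                          bud_mito_volume, dump_occupancy) {
  stopifnot(total_mito_volume > 0, unit_mito_volume > 0, bud_mito_volume > 0,
            dump_occupancy > 0, dump_occupancy < 1)
  n_total <- as.integer(floor(total_mito_volume / unit_mito_volume))
  n_inherit <- as.integer(floor(bud_mito_volume / unit_mito_volume))
  n_dump <- as.integer(floor(dump_occupancy * n_total))
  if (n_total < 1L || n_inherit < 1L || n_dump < 1L)
    stop("degenerate configuration: derived particle counts must all be >= 1 ",
         sprintf("(got n_total = %d, n_inherit = %d, n_dump = %d)",
                 n_total, n_inherit, n_dump))
  list(n_total = n_total, n_inherit = n_inherit, n_dump = n_dump)
}

#' Condition profile: the law triple of one mitochondrial condition
#'
#' @param fission_law,fusion_law,diffusion_law [rate_law()] objects.
#' @param label One of `"WT"`, `"DUMP-"`, `"DUMP+"`.
#' @return Object of class `condition_profile`.
#' @export
condition_profile <- function(fission_law, fusion_law, diffusion_law, label) {
  stopifnot(inherits(fission_law, "rate_law"),
            inherits(fusion_law, "rate_law"),
            inherits(diffusion_law, "rate_law"),
            is.character(label), length(label) == 1L)
  structure(list(fission_law = fission_law, fusion_law = fusion_law,
                 diffusion_law = diffusion_law, label = label),
            class = "condition_profile")
}

#' Calibrated condition profiles
#'
#' The calibrated slope/intercept pairs of the fission, fusion and diffusion
#' laws for the three mitochondrial conditions: `wt` (no aggregates in the
#' cell), `dump_neg` (aggregate-free mitochondria in aggregate-bearing
#' cells) and `dump_pos` (aggregate-bearing mitochondria).
#'
#' @return Named list of three [condition_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    wt = condition_profile(
      fission_law   = rate_law(1.28e-3, -1.67e-3),
      fusion_law    = rate_law(-3.72e-4, 8.04e-3),
      diffusion_law = rate_law(-3.90e-5, 9.50e-4),
      label = "WT"),
    dump_neg = condition_profile(
      fission_law   = rate_law(1.57e-3, -5.48e-4),
      fusion_law    = rate_law(-7.93e-4, 1.19e-2),
      diffusion_law = rate_law(1.74e-4, 1.32e-3),
      label = "DUMP-"),
    dump_pos = condition_profile(
      fission_law   = rate_law(1.19e-3, -1.33e-3),
      fusion_law    = rate_law(-1.59e-4, 7.15e-3),
      diffusion_law = rate_law(-4.10e-5, 9.57e-4),
      label = "DUMP+")
  )
}

#' Full calibrated parameter set
#'
#' Bundles the primitive measurements, the run schedule and the condition
#' profiles, and computes every derived constant: particle radius, box side,
#' and the particle counts.  Defaults are the calibrated values used
#' throughout the package.
#'
#' @param unit_mito_volume Unit mitochondrion volume, um^3.
#' @param mother_cell_volume Mean mother-cell volume, um^3.
#' @param total_mito_volume Mean total mitochondrial volume, um^3.
#' @param bud_mito_volume Mean bud mitochondrial volume, um^3.
#' @param dump_occupancy Fraction of mitochondrial volume occupied by DUMP.
#' @param dt_sim Simulation timestep, s.
#' @param dt_expt Experimental movie frame interval, s.
#' @param t_equil Equilibration phase duration, s.
#' @param t_eval Evaluation phase duration, s.
#' @param profiles Named list with elements `wt`, `dump_neg`, `dump_pos`
#'   (see [default_profiles()]).
#' @param prob_model `"linear"` for `min(1, rate*dt)` per-step probabilities
#'   or `"exact"` for `1 - exp(-rate*dt)`.
#' @param diffusion_floor Lower clamp on the diffusion constant, um^2/s,
#'   keeping step sizes defined where the linear law goes negative.
#' @return Object of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$n_total    # 54
#' p$n_inherit  # 15
#' p$n_dump     # 6
#' @export
sim_params <- function(unit_mito_volume = 0.12,
                       mother_cell_volume = 54.04,
                       total_mito_volume = 6.56,
                       bud_mito_volume = 1.83,
                       dump_occupancy = 0.122,
                       dt_sim = 0.1,
                       dt_expt = 10,
                       t_equil = 1800,
                       t_eval = 5400,
                       profiles = default_profiles(),
                       prob_model = c("linear", "exact"),
                       diffusion_floor = 1e-12) {
  prob_model <- match.arg(prob_model)
  stopifnot(dt_sim > 0, dt_expt > 0, t_equil >= 0, t_eval >= 0,
            diffusion_floor > 0,
            is.list(profiles),
            all(c("wt", "dump_neg", "dump_pos") %in% names(profiles)))
  for (pr in profiles[c("wt", "dump_neg", "dump_pos")])
    stopifnot(inherits(pr, "condition_profile"))
  geom <- derive_geometry(mother_cell_volume)
  counts <- derive_counts(total_mito_volume, unit_mito_volume,
                          bud_mito_volume, dump_occupancy)
  structure(c(
    list(unit_mito_volume = unit_mito_volume,
         mother_cell_volume = mother_cell_volume,
         total_mito_volume = total_mito_volume,
         bud_mito_volume = bud_mito_volume,
         dump_occupancy = dump_occupancy,
         dt_sim = dt_sim, dt_expt = dt_expt,
         t_equil = t_equil, t_eval = t_eval, t_total = t_equil + t_eval,
         profiles = profiles,
         particle_radius = derive_particle_radius(unit_mito_volume),
         mother_radius = geom$mother_radius,
         mother_surface_area = geom$mother_surface_area,
         box_side = geom$box_side,
         prob_model = prob_model,
         diffusion_floor = diffusion_floor),
    counts), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  box side L = %.3f um, particle radius = %.3f um\n",
              x$box_side, x$particle_radius))
  cat(sprintf("  particles: total %d, inherited %d, DUMP-marked %d\n",
              x$n_total, x$n_inherit, x$n_dump))
  cat(sprintf("  schedule: %g s equilibration + %g s evaluation at dt = %g s\n",
              x$t_equil, x$t_eval, x$dt_sim))
  cat(sprintf("  per-step probability model: %s\n", x$prob_model))
  invisible(x)
}

# 3x2 matrix (rows fission, fusion, diffusion; cols slope, intercept) for C++
law_matrix <- function(profile) {
  rbind(c(profile$fission_law$slope, profile$fission_law$intercept),
        c(profile$fusion_law$slope, profile$fusion_law$intercept),
        c(profile$diffusion_law$slope, profile$diffusion_law$intercept))
}
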