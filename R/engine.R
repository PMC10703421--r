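#' Construct a simulation state
#'
#' A state holds particle positions on the periodic box, DUMP marks, the
#' connectivity forest (edge list) and the clock.  Particles are identified
#' by their row index.
#'
#' @param pos n x 2 numeric matrix of positions in `[0, box_side)`.
#' @param marked Logical vector of length n: DUMP-marked particles.
#' @param edges m x 2 integer matrix of undirected forest edges (particle
#'   ids); may have zero rows.
#' @param box_side Side length of the periodic square box, um.
#' @param particle_radius Particle radius, um.
#' @param time Clock, s.
#' @return Object of class `sim_state`.
#' @export
sim_state <- function(pos, marked, edges, box_side, particle_radius,
                      time = 0) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  edges <- matrix(as.integer(edges), ncol = 2)
  state <- structure(
    list(time = time, pos = pos, marked = as.logical(marked), edges = edges,
         box_side = box_side, particle_radius = particle_radius),
    class = "sim_state")
  validate_state(state)
  state
}

#' Check the structural invariants of a state
#'
#' Verifies that positions lie in the box, the mark vector matches the
#' particle count, edge endpoints are valid, and the connectivity graph is a
#' forest (number of components + number of edges = number of particles).
#'
#' @param state A [sim_state()].
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state) {
  n <- nrow(state$pos)
  stopifnot(ncol(state$pos) == 2, length(state$marked) == n,
            all(is.finite(state$pos)),
            all(state$pos >= 0), all(state$pos < state$box_side))
  m <- nrow(state$edges)
  if (m > 0) {
    stopifnot(all(state$edges >= 1), all(state$edges <= n),
              all(state$edges[, 1] != state$edges[, 2]))
  }
  comp <- component_membership(state)
  n_comp <- length(unique(comp))
  if (n_comp + m != n)
    stop("connectivity graph is not a forest: ", n, " particles, ",
         m, " edges, ", n_comp, " components")
  invisible(state)
}

#' @export
print.sim_state <- function(x, ...) {
  comp <- component_membership(x)
  cat(sprintf(
    "<sim_state> t = %g s: %d particles (%d marked), %d edges, %d networks\n",
    x$time, nrow(x$pos), sum(x$marked), nrow(x$edges),
    length(unique(comp))))
  invisible(x)
}

# adjacency list over forest edges (list of integer vectors, index = particle)
state_adjacency <- function(state, n = nrow(state$pos)) {
  adj <- vector("list", n)
  e <- state$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      a <- e[k, 1]; b <- e[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

#' Component membership of every particle
#'
#' Connected components of the forest; labels are the smallest particle id
#' in each component, so labels are stable across calls.
#'
#' @param state A [sim_state()].
#' @return Integer vector of component labels, one per particle.
#' @export
component_membership <- function(state) {
  n <- nrow(state$pos)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- state$edges
  if (nrow(e) > 0) {
    for (k in seq_len(nrow(e))) {
      ra <- find(e[k, 1]); rb <- find(e[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(stats::ave(seq_len(n), roots, FUN = min))
}

#' Minimum-image distance between two particles
#'
#' @param state A [sim_state()].
#' @param i,j Particle ids.
#' @return Euclidean distance under the periodic minimum-image convention.
#' @export
min_image_distance <- function(state, i, j) {
  L <- state$box_side
  d <- state$pos[i, ] - state$pos[j, ]
  d <- d - L * round(d / L)
  sqrt(sum(d^2))
}

#' Biased-fission configuration
#'
#' Controls where fission cuts the forest.  In `random` mode every edge of
#' the splitting network is equally likely.  In `biased` mode a fraction
#' `biased_fraction` of fission events is restricted to boundary edges (one
#' endpoint DUMP-marked, one unmarked).  In `adjacent` mode that fraction is
#' restricted to edges one hop outside the marked set.  A marked network
#' with no eligible edge skips the event; an unmarked network always splits
#' at a uniformly random edge.
#'
#' @param placement_mode `"random"`, `"biased"` or `"adjacent"`.
#' @param biased_fraction Fraction of fission events that use the restricted
#'   placement, in `[0, 1]`.
#' @return Object of class `bias_config`.
#' @export
bias_config <- function(placement_mode = c("random", "biased", "adjacent"),
                        biased_fraction = 0) {
  placement_mode <- match.arg(placement_mode)
  stopifnot(is.numeric(biased_fraction), length(biased_fraction) == 1L,
            biased_fraction >= 0, biased_fraction <= 1)
  if (placement_mode == "random") biased_fraction <- 0
  structure(list(placement_mode = placement_mode,
                 biased_fraction = biased_fraction),
            class = "bias_config")
}

bias_mode_code <- function(bias) {
  switch(bias$placement_mode, random = 0L, biased = 1L, adjacent = 2L)
}

#' DUMP seeding specification
#'
#' At the end of equilibration `total_marked` particles are marked as
#' DUMP-containing, arranged as a requested number of clusters (connected
#' runs of marked particles) grown by flood fill along forest edges.  The
#' cluster count can be fixed or drawn per run from a discrete distribution
#' over 1..`total_marked`; the shipped default emulates the observed
#' per-cell DUMP-count distribution (probabilities proportional to
#' 70, 170, 184, 134, 52, 16 for 1-6 clusters).  `singlets` mode marks
#' `total_marked` pairwise non-adjacent particles (equivalent to clustered
#' mode with as many clusters as marks).
#'
#' @param mode `"clustered"` or `"singlets"`.
#' @param cluster_count Fixed number of clusters (ignored in singlets mode).
#' @param cluster_count_distribution Numeric vector of weights over cluster
#'   counts 1, 2, ...; used when `cluster_count` is `NULL`.
#' @param total_marked Total number of particles to mark; defaults to the
#'   parameter set's `n_dump` at seeding time.
#' @return Object of class `seeding_spec`.
#' @export
seeding_spec <- function(mode = c("clustered", "singlets"),
                         cluster_count = NULL,
                         cluster_count_distribution = NULL,
                         total_marked = NULL) {
  mode <- match.arg(mode)
  if (!is.null(cluster_count))
    stopifnot(cluster_count >= 1, cluster_count == floor(cluster_count))
  if (!is.null(cluster_count_distribution))
    stopifnot(is.numeric(cluster_count_distribution),
              all(cluster_count_distribution >= 0),
              sum(cluster_count_distribution) > 0)
  if (mode == "clustered" && is.null(cluster_count) &&
      is.null(cluster_count_distribution))
    cluster_count_distribution <- dump_count_distribution()
  structure(list(mode = mode, cluster_count = cluster_count,
                 cluster_count_distribution = cluster_count_distribution,
                 total_marked = total_marked),
            class = "seeding_spec")
}

#' Default DUMP cluster-count distribution
#'
#' Placeholder (synthetic) distribution of the number of DUMP clusters per
#' cell under steady-state constitutive aggregate expression, which
#' averages 1-2 DUMPs per cell: a geometric distribution with success
#' probability 2/3 (mean 1.5) truncated to counts 1-6 and renormalized.
#' Replace with your own measured distribution via [seeding_spec()] when
#' available.
#'
#' @return Numeric vector of probabilities over cluster counts 1 to 6.
#' @export
dump_count_distribution <- function() {
  w <- (2 / 3) * (1 / 3)^(0:5)
  w / sum(w)
}

#' Evaluation-phase parameter configuration
#'
#' Selects, for the post-seeding phase, which condition's fission/fusion
#' laws and which diffusion laws apply, and the fission bias.  Under
#' `"mitofluc"`, networks containing a marked particle use the DUMP+ laws
#' and unmarked networks the DUMP- laws; under `"wt"` all networks use the
#' WT laws.  The default is the aggregate-expression condition with biased
#' fission fully on.
#'
#' @param fission_fusion `"mitofluc"` or `"wt"`.
#' @param diffusion `"mitofluc"` or `"wt"`.
#' @param bias A [bias_config()].
#' @param label Optional human-readable label for records.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(fission_fusion = c("mitofluc", "wt"),
                       diffusion = c("mitofluc", "wt"),
                       bias = bias_config("biased", 1),
                       label = NULL) {
  fission_fusion <- match.arg(fission_fusion)
  diffusion <- match.arg(diffusion)
  stopifnot(inherits(bias, "bias_config"))
  if (is.null(label))
    label <- sprintf("fisfus=%s dif=%s bias=%s(%g)", fission_fusion,
                     diffusion, bias$placement_mode, bias$biased_fraction)
  structure(list(fission_fusion = fission_fusion, diffusion = diffusion,
                 bias = bias, label = label), class = "sim_config")
}

# law matrices for the unmarked-/marked-network conditions of a phase.
# config = NULL means the equilibration phase: WT laws, no marks yet.
phase_laws <- function(params, config = NULL) {
  pr <- params$profiles
  if (is.null(config)) {
    wt <- law_matrix(pr$wt)
    return(list(unmarked = wt, marked = wt))
  }
  ff_un <- if (config$fission_fusion == "mitofluc") pr$dump_neg else pr$wt
  ff_mk <- if (config$fission_fusion == "mitofluc") pr$dump_pos else pr$wt
  di_un <- if (config$diffusion == "mitofluc") pr$dump_neg else pr$wt
  di_mk <- if (config$diffusion == "mitofluc") pr$dump_pos else pr$wt
  un <- law_matrix(ff_un); un[3, ] <- law_matrix(di_un)[3, ]
  mk <- law_matrix(ff_mk); mk[3, ] <- law_matrix(di_mk)[3, ]
  list(unmarked = un, marked = mk)
}

events_df <- function(mat) {
  df <- as.data.frame(mat)
  df$event_type <- c("fission", "fusion")[df$event_type]
  df
}

#' Initialize a simulation state
#'
#' Seeds `n_total` unmarked singleton particles at independent uniform
#' positions in the periodic box, with an empty edge set and clock zero.
#'
#' @param params A [sim_params()].
#' @param seed Optional integer passed to [set.seed()]; `NULL` leaves the
#'   RNG stream untouched.
#' @return A [sim_state()].
#' @export
initialize_state <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_total
  pos <- matrix(stats::runif(2 * n, 0, params$box_side), ncol = 2)
  sim_state(pos, marked = rep(FALSE, n),
            edges = matrix(integer(0), ncol = 2),
            box_side = params$box_side,
            particle_radius = params$particle_radius, time = 0)
}

#' Advance diffusion by one timestep
#'
#' Every network is translated as a rigid body by a vector of length
#' `sqrt(4 * D(v) * dt)` at an independent uniform angle, where `D(v)` is
#' the active diffusion law at the network's 3D-equivalent volume; particle
#' coordinates are wrapped back into the box.
#'
#' @param state A [sim_state()].
#' @param params A [sim_params()].
#' @param dt Timestep, s.
#' @param config `NULL` for the equilibration (WT) phase, or a
#'   [sim_config()] for the evaluation phase.
#' @return The updated state.
#' @export
diffuse <- function(state, params, dt = params$dt_sim, config = NULL) {
  laws <- phase_laws(params, config)
  state$pos <- cpp_diffuse(state$pos, state$edges,
                           as.integer(state$marked), state$box_side,
                           params$unit_mito_volume, dt,
                           laws$unmarked, laws$marked,
                           params$diffusion_floor)
  state$time <- state$time + dt
  state
}

#' Attempt fusion events for one timestep
#'
#' Every unordered pair of distinct networks whose closest particles are
#' within one particle diameter (`2 * particle_radius`, minimum image)
#' undergoes a Bernoulli trial; the trial rate is the mean of each
#' partner's own fusion law at its volume.  On success an edge joins the
#' closest particle pair.  Contact pairs are processed in random order with
#' membership recomputed after each success, so the forest is preserved.
#'
#' @inheritParams diffuse
#' @param force_prob Override the trial probability (for tests); `NULL`
#'   uses the rate laws.
#' @return The updated state; fusion events of this step are attached as
#'   `attr(state, "events")`.
#' @export
attempt_fusions <- function(state, params, dt = params$dt_sim, config = NULL,
                            force_prob = NULL) {
  laws <- phase_laws(params, config)
  res <- cpp_fusions(state$pos, state$edges, as.integer(state$marked),
                     state$box_side, state$particle_radius,
                     params$unit_mito_volume, dt, laws$unmarked, laws$marked,
                     params$prob_model == "exact",
                     if (is.null(force_prob)) -1 else force_prob,
                     state$time)
  state$edges <- res$edges
  attr(state, "events") <- events_df(res$events)
  state
}

#' Attempt fission events for one timestep
#'
#' Every network of more than one particle undergoes a Bernoulli trial at
#' its active fission law's per-step probability; on success one edge is
#' removed, splitting the network in two.  Placement follows the
#' [bias_config()]: uniform over all edges, or (for the biased fraction of
#' events) uniform over DUMP-boundary edges, or over edges one hop outside
#' the marked set in adjacent mode.
#'
#' @inheritParams attempt_fusions
#' @param bias A [bias_config()]; defaults to the one in `config`, or no
#'   bias.
#' @return The updated state; fission events attached as
#'   `attr(state, "events")`.
#' @export
attempt_fissions <- function(state, params, dt = params$dt_sim,
                             config = NULL, bias = NULL, force_prob = NULL) {
  if (is.null(bias)) bias <- if (is.null(config)) bias_config() else config$bias
  laws <- phase_laws(params, config)
  res <- cpp_fissions(state$pos, state$edges, as.integer(state$marked),
                      params$unit_mito_volume, dt, laws$unmarked, laws$marked,
                      bias$biased_fraction, bias_mode_code(bias),
                      params$prob_model == "exact",
                      if (is.null(force_prob)) -1 else force_prob,
                      state$time)
  state$edges <- res$edges
  attr(state, "events") <- events_df(res$events)
  state
}

# Sample a cluster count for one run from a seeding spec.
draw_cluster_count <- function(spec, total_marked) {
  if (spec$mode == "singlets") return(total_marked)
  if (!is.null(spec$cluster_count)) {
    k <- spec$cluster_count
  } else {
    w <- spec$cluster_count_distribution
    k <- sample.int(length(w), 1L, prob = w)
  }
  if (k > total_marked)
    stop("requested cluster count (", k, ") exceeds total marked particles (",
         total_marked, ")")
  as.integer(k)
}

#' Seed DUMP marks onto an equilibrated state
#'
#' Marks `total_marked` particles arranged as exactly `k` clusters
#' (connected runs of marked particles through forest edges).  Seeds are
#' drawn at random, then flood fill grows clusters one adjacent particle at
#' a time in round-robin order; any draw in which clusters would touch (and
#' so fuse) is rejected and re-sampled, up to `max_tries` attempts.
#'
#' @param state An unmarked [sim_state()].
#' @param spec A [seeding_spec()].
#' @param params A [sim_params()]; supplies the default `total_marked`.
#' @param max_tries Rejection-sampling cap before aborting.
#' @return The state with marks set; the realized cluster count is attached
#'   as `attr(state, "n_clusters")`.
#' @export
seed_dumps <- function(state, spec, params, max_tries = 10000) {
  stopifnot(inherits(spec, "seeding_spec"), !any(state$marked))
  n <- nrow(state$pos)
  total <- spec$total_marked
  if (is.null(total)) total <- params$n_dump
  if (total < 1 || total > n)
    stop("seeding failed: ", total, " marked particles requested but the ",
         "state has ", n, " particles")
  k <- draw_cluster_count(spec, total)
  adj <- state_adjacency(state, n)

  for (try in seq_len(max_tries)) {
    seeds <- sample.int(n, k)
    cluster_of <- integer(n)                 # 0 = unmarked
    cluster_of[seeds] <- seq_len(k)
    # seeds adjacent to each other would start as one merged cluster
    if (any(vapply(seeds, function(s)
      any(cluster_of[adj[[s]]] != 0 & cluster_of[adj[[s]]] != cluster_of[s]),
      logical(1)))) next
    n_marked <- k
    stuck <- rep(FALSE, k)
    failed <- FALSE
    cl <- 0L
    while (n_marked < total) {
      if (all(stuck)) { failed <- TRUE; break }
      cl <- (cl %% k) + 1L
      if (stuck[cl]) next
      members <- which(cluster_of == cl)
      frontier <- unique(unlist(adj[members]))
      frontier <- frontier[cluster_of[frontier] == 0L]
      # exclude growth that would touch (fuse with) another cluster
      if (length(frontier) > 0)
        frontier <- frontier[vapply(frontier, function(p) {
          nb <- cluster_of[adj[[p]]]
          !any(nb != 0L & nb != cl)
        }, logical(1))]
      if (length(frontier) == 0) { stuck[cl] <- TRUE; next }
      pick <- frontier[sample.int(length(frontier), 1L)]
      cluster_of[pick] <- cl
      n_marked <- n_marked + 1L
    }
    if (!failed && n_marked == total) {
      state$marked <- cluster_of != 0L
      attr(state, "n_clusters") <- k
      return(state)
    }
  }
  stop("seeding failed: could not place ", total, " marked particles as ", k,
       " clusters within ", max_tries, " attempts")
}

#' Run one full simulation
#'
#' The run schedule: `t_equil` seconds of equilibration under WT laws with
#' bias off and no marks; DUMP seeding; `t_eval` seconds under the
#' configured evaluation laws and bias.  Per step, networks diffuse, then
#' fusions are attempted, then fissions.  Structural events and periodic
#' snapshots are recorded.
#'
#' @param params A [sim_params()].
#' @param config A [sim_config()] for the evaluation phase.
#' @param seeding A [seeding_spec()].
#' @param seed Integer seed; the single RNG stream of the run.
#' @param snapshot_dt Snapshot cadence in seconds (a multiple of `dt_sim`),
#'   or `NA` to record only the phase-boundary snapshots.
#' @param record_events Record the structural event log.
#' @param snapshot_on_event Also snapshot at every structural event.
#' @return Object of class `sim_record`: event log, snapshots, the edge set
#'   at seeding time, the final state and run metadata.
#' @export
run_simulation <- function(params, config = sim_config(),
                           seeding = seeding_spec(), seed,
                           snapshot_dt = params$dt_expt,
                           record_events = TRUE,
                           snapshot_on_event = FALSE) {
  stopifnot(inherits(params, "sim_params"), inherits(config, "sim_config"))
  set.seed(seed)
  state <- initialize_state(params)
  snap_every <- if (is.na(snapshot_dt)) 0L else {
    se <- as.integer(round(snapshot_dt / params$dt_sim))
    stopifnot(se >= 1)
    se
  }
  laws_eq <- phase_laws(params, NULL)
  n_steps_eq <- as.integer(round(params$t_equil / params$dt_sim))
  res1 <- cpp_run(state$pos, state$edges, as.integer(state$marked),
                  state$box_side, state$particle_radius,
                  params$unit_mito_volume, params$dt_sim, n_steps_eq,
                  laws_eq$unmarked, laws_eq$marked, 0, 0L,
                  params$prob_model == "exact", snap_every, record_events,
                  snapshot_on_event, 0, params$diffusion_floor)
  state$pos <- res1$pos
  state$edges <- res1$edges
  state$time <- res1$time

  state <- seed_dumps(state, seeding, params)
  n_clusters <- attr(state, "n_clusters")
  edges_at_seed <- state$edges

  laws_ev <- phase_laws(params, config)
  n_steps_ev <- as.integer(round(params$t_eval / params$dt_sim))
  res2 <- cpp_run(state$pos, state$edges, as.integer(state$marked),
                  state$box_side, state$particle_radius,
                  params$unit_mito_volume, params$dt_sim, n_steps_ev,
                  laws_ev$unmarked, laws_ev$marked,
                  config$bias$biased_fraction, bias_mode_code(config$bias),
                  params$prob_model == "exact", snap_every, record_events,
                  snapshot_on_event, params$t_equil, params$diffusion_floor)
  final <- state
  final$pos <- res2$pos
  final$edges <- res2$edges
  final$time <- res2$time

  snaps <- rbind(res1$snapshots, res2$snapshots)
  if (is.na(snapshot_dt)) {
    # keep the seeding-time and terminal snapshots only
    boundary <- function(st) cbind(
      time_s = st$time, particle_id = seq_len(nrow(st$pos)),
      x_um = st$pos[, 1], y_um = st$pos[, 2],
      dump_marked = as.numeric(st$marked),
      component_id = component_membership(st))
    snaps <- if (final$time > state$time)
      rbind(boundary(state), boundary(final)) else boundary(state)
  } else {
    # the seeding-time snapshot supersedes the pre-seeding one at t_equil
    drop <- snaps[, "time_s"] == params$t_equil
    seedsnap <- cbind(
      time_s = params$t_equil, particle_id = seq_len(nrow(state$pos)),
      x_um = state$pos[, 1], y_um = state$pos[, 2],
      dump_marked = as.numeric(state$marked),
      component_id = component_membership(state))
    snaps <- rbind(snaps[!drop, , drop = FALSE], seedsnap)
    snaps <- snaps[order(snaps[, "time_s"], snaps[, "particle_id"]), ,
                   drop = FALSE]
  }
  events <- events_df(rbind(res1$events, res2$events))

  structure(list(
    meta = list(seed = seed, config_label = config$label,
                seeding_mode = seeding$mode, n_clusters = n_clusters,
                events_recorded = record_events,
                parameter_hash = params_hash(params)),
    params = params, config = config, seeding = seeding,
    events = events,
    snapshots = as.data.frame(snaps),
    edges_at_seed = edges_at_seed,
    seed_time = params$t_equil,
    final_state = final), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf(
    "<sim_record> seed %s, %s; %d events, %d snapshot times, t = %g s\n",
    format(x$meta$seed), x$meta$config_label, nrow(x$events),
    length(unique(x$snapshots$time_s)), x$final_state$time))
  invisible(x)
}

# order-sensitive checksum of every numeric parameter and law coefficient
params_hash <- function(params) {
  nums <- unlist(params[vapply(params, is.numeric, logical(1))])
  laws <- unlist(lapply(params$profiles, function(p)
    c(p$fission_law$slope, p$fission_law$intercept,
      p$fusion_law$slope, p$fusion_law$intercept,
      p$diffusion_law$slope, p$diffusion_law$intercept)))
  s <- paste(format(c(nums, laws), digits = 15), collapse = ",")
  b <- utf8ToInt(s)
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% .Machine$integer.max)
}

#' Reconstruct the state at a recorded time
#'
#' Positions and marks come from the snapshot at `time`; the edge set is
#' rebuilt by replaying the event log from the start of the run (the run
#' begins edgeless, so the replayed set is exact).
#'
#' @param record A [run_simulation()] record.
#' @param time A time present in the record's snapshots, s.
#' @return A [sim_state()].
#' @export
state_at <- function(record, time) {
  snaps <- record$snapshots
  rows <- snaps$time_s == time
  if (!any(rows))
    stop("no snapshot recorded at t = ", time, " s")
  sub <- snaps[rows, ]
  sub <- sub[order(sub$particle_id), ]
  if (!isTRUE(record$meta$events_recorded)) {
    edges <- if (time == record$seed_time) record$edges_at_seed
             else if (time == record$final_state$time) record$final_state$edges
             else stop("record has no event log; only the seeding-time and ",
                       "final states can be reconstructed")
    return(sim_state(pos = cbind(sub$x_um, sub$y_um),
                     marked = sub$dump_marked == 1, edges = edges,
                     box_side = record$params$box_side,
                     particle_radius = record$params$particle_radius,
                     time = time))
  }
  ev <- record$events
  ev <- ev[ev$time_s <= time, , drop = FALSE]
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(ev) > 0) {
    keep <- rep(TRUE, 0)
    elist <- list()
    for (k in seq_len(nrow(ev))) {
      a <- ev$particle_a[k]; b <- ev$particle_b[k]
      if (ev$event_type[k] == "fusion") {
        elist[[length(elist) + 1L]] <- c(a, b)
      } else {
        hit <- which(vapply(elist, function(e)
          (e[1] == a && e[2] == b) || (e[1] == b && e[2] == a), logical(1)))
        if (length(hit) == 0)
          stop("event replay inconsistency: fission of a missing edge")
        elist[[hit[1]]] <- NULL
      }
    }
    if (length(elist) > 0)
      edges <- do.call(rbind, elist)
  }
  sim_state(pos = cbind(sub$x_um, sub$y_um), marked = sub$dump_marked == 1,
            edges = edges, box_side = record$params$box_side,
            particle_radius = record$params$particle_radius, time = time)
}
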