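#' Largest mitochondrial network in a state
#'
#' Returns the particle ids of the component with the most particles; ties
#' are broken uniformly at random from the active RNG stream, so no
#' particle-id ordering artifact biases downstream selection.
#'
#' @param state A [sim_state()].
#' @return Integer vector of particle ids.
#' @export
largest_component <- function(state) {
  comp <- component_membership(state)
  sizes <- table(comp)
  big <- names(sizes)[sizes == max(sizes)]
  lab <- if (length(big) == 1L) big else big[sample.int(length(big), 1L)]
  which(comp == as.integer(lab))
}

# BFS distances from `from` over the component's adjacency; -1 = unreached
bfs_distances <- function(adj, from, n) {
  dist <- rep(-1L, n)
  dist[from] <- 0L
  queue <- from
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]; head <- head + 1L
    for (v in adj[[u]]) {
      if (dist[v] < 0L) {
        dist[v] <- dist[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  dist
}

#' Tip of the longest branch of a tree component
#'
#' The longest branch is a tree-diameter path in hop count (all bonds have
#' the same physical length, one contact distance).  Computed by the double
#' breadth-first sweep: from a random member, the farthest node is an
#' endpoint of some maximum-length simple path.  Ties are broken uniformly
#' at random.
#'
#' @param state A [sim_state()].
#' @param component Integer vector of the component's particle ids.
#' @return A single particle id: one endpoint of a maximum-length path.
#' @export
longest_branch_tip <- function(state, component) {
  n <- nrow(state$pos)
  if (length(component) == 1L) return(component)
  adj <- state_adjacency(state, n)
  start <- component[sample.int(length(component), 1L)]
  d1 <- bfs_distances(adj, start, n)
  far <- component[d1[component] == max(d1[component])]
  far[sample.int(length(far), 1L)]
}

#' Select the inherited particles from a branch tip
#'
#' Breadth-first traversal of the tree from the tip, collecting particles
#' in traversal order until `n_inherit` are collected or the component is
#' exhausted (a smaller component is inherited whole; no particles are
#' added from elsewhere).  Within each BFS frontier the neighbor order is
#' randomized.
#'
#' @param state A [sim_state()].
#' @param tip Particle id returned by [longest_branch_tip()].
#' @param n_inherit Number of particles to inherit.
#' @return Integer vector of inherited particle ids (possibly empty).
#' @export
select_inherited <- function(state, tip, n_inherit) {
  if (n_inherit <= 0) return(integer(0))
  n <- nrow(state$pos)
  adj <- state_adjacency(state, n)
  visited <- rep(FALSE, n)
  visited[tip] <- TRUE
  order_out <- tip
  queue <- tip
  head <- 1L
  while (head <= length(queue) && length(order_out) < n_inherit) {
    u <- queue[head]; head <- head + 1L
    nb <- adj[[u]]
    nb <- nb[!visited[nb]]
    if (length(nb) > 1L) nb <- nb[sample.int(length(nb))]
    for (v in nb) {
      if (!visited[v]) {
        visited[v] <- TRUE
        order_out <- c(order_out, v)
        queue <- c(queue, v)
        if (length(order_out) >= n_inherit) break
      }
    }
  }
  order_out[seq_len(min(n_inherit, length(order_out)))]
}

#' Apply the two-step inheritance algorithm to a state
#'
#' Mimics the observed extrusion of a mitochondrial branch into the bud:
#' the largest network is identified, the tip of its longest branch found,
#' and `n_inherit` particles selected from the tip by breadth-first search.
#' The state is not modified.  Inheritance of any DUMP-marked particle is a
#' retention failure.
#'
#' @param state A [sim_state()].
#' @param n_inherit Number of particles the bud receives.
#' @return Object of class `inheritance_result` with fields
#'   `evaluation_time`, `inherited_particle_ids`, `inherited_count`,
#'   `contains_dump` and `largest_component_size`.
#' @export
evaluate_inheritance <- function(state, n_inherit) {
  comp <- largest_component(state)
  tip <- longest_branch_tip(state, comp)
  inherited <- select_inherited(state, tip, n_inherit)
  structure(list(
    evaluation_time = state$time,
    inherited_particle_ids = inherited,
    inherited_count = length(inherited),
    contains_dump = any(state$marked[inherited]),
    largest_component_size = length(comp)), class = "inheritance_result")
}

#' @export
print.inheritance_result <- function(x, ...) {
  cat(sprintf(
    "<inheritance_result> t = %g s: %d particles inherited (largest network %d); DUMP inherited: %s\n",
    x$evaluation_time, x$inherited_count, x$largest_component_size,
    x$contains_dump))
  invisible(x)
}

#' Inheritance outcome over the course of a run
#'
#' Applies [evaluate_inheritance()] to the reconstructed state at every
#' cadence tick from seeding time to the end of the run, emulating
#' spontaneous inheritance at each moment.
#'
#' @param record A [run_simulation()] record with snapshot coverage at the
#'   requested cadence.
#' @param n_inherit Number of particles the bud receives; defaults to the
#'   record's calibrated value.
#' @param cadence Evaluation interval, s.
#' @return `data.frame` with one row per evaluation time: `time_s`,
#'   `inherited_count`, `contains_dump`, `largest_component_size`.
#' @export
inheritance_timeseries <- function(record, n_inherit = NULL, cadence = 60) {
  if (is.null(n_inherit)) n_inherit <- record$params$n_inherit
  times <- seq(record$seed_time, record$final_state$time, by = cadence)
  missing <- setdiff(times, unique(record$snapshots$time_s))
  if (length(missing) > 0)
    stop("record lacks snapshots at the requested cadence (first missing: ",
         missing[1], " s)")
  rows <- lapply(times, function(t) {
    r <- evaluate_inheritance(state_at(record, t), n_inherit)
    data.frame(time_s = t, inherited_count = r$inherited_count,
               contains_dump = r$contains_dump,
               largest_component_size = r$largest_component_size)
  })
  do.call(rbind, rows)
}
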