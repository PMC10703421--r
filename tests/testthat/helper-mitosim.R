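# Shared fixtures and independent oracles for the test suite.

default_params <- sim_params()

# a small state built by hand: positions on a grid, explicit edges/marks
hand_state <- function(pos, edges = matrix(integer(0), ncol = 2),
                       marked = rep(FALSE, nrow(pos)),
                       params = default_params) {
  sim_state(pos, marked, edges, box_side = params$box_side,
            particle_radius = params$particle_radius)
}

# chain state with an explicit mark pattern
marked_chain <- function(marks, params = default_params) {
  st <- make_fixture("chain", length(marks), params)
  st$marked <- as.logical(marks)
  st
}

# independent oracle: tree eccentricity/diameter via igraph on a state
oracle_diameter <- function(state, members) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = state$edges[, 1], to = state$edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(state$pos))))
  sub <- igraph::induced_subgraph(g, as.character(members))
  igraph::diameter(sub, unconnected = FALSE)
}

oracle_ecc <- function(state, members, v) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = state$edges[, 1], to = state$edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(state$pos))))
  sub <- igraph::induced_subgraph(g, as.character(members))
  max(igraph::distances(sub, v = as.character(v)))
}

# random labelled tree on n nodes (uniform via Pruefer sequence)
random_tree_edges <- function(n) {
  if (n == 1) return(matrix(integer(0), ncol = 2))
  if (n == 2) return(matrix(c(1L, 2L), ncol = 2))
  prufer <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1L, n)
  for (p in prufer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(prufer)) {
    leaf <- min(which(degree == 1L))
    edges[i, ] <- c(leaf, prufer[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[prufer[i]] <- degree[prufer[i]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# state whose forest is the given edge set, positions immaterial
tree_state <- function(edges, n, marked = rep(FALSE, n),
                       params = default_params) {
  set_pos <- matrix(stats::runif(2 * n, 0, params$box_side), ncol = 2)
  sim_state(set_pos, marked, edges, box_side = params$box_side,
            particle_radius = params$particle_radius)
}

# minimum-image pairwise distance matrix of a state
pairwise_mi <- function(state, ids = seq_len(nrow(state$pos))) {
  outer(ids, ids, Vectorize(function(i, j) min_image_distance(state, i, j)))
}

# run terminal-inheritance outcomes for a batch of seeds
terminal_outcomes <- function(params, config, seeding, seeds) {
  vapply(seeds, function(s) {
    rec <- run_simulation(params, config, seeding, seed = s,
                          snapshot_dt = NA, record_events = FALSE)
    evaluate_inheritance(rec$final_state, params$n_inherit)$contains_dump
  }, logical(1))
}

# displacement of particle 1 between two states, minimum image
min_image_distance_between <- function(st1, st2, L) {
  d <- st2$pos[1, ] - st1$pos[1, ]
  d <- d - L * round(d / L)
  sqrt(sum(d^2))
}

# profiles whose diffusion laws are identically zero
within_profile_diffusion_zero <- function() {
  pr <- default_profiles()
  for (nm in names(pr)) pr[[nm]]$diffusion_law <- rate_law(0, 0)
  pr
}

# canonical edge representation: rows sorted within and across
sort_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  e <- t(apply(edges, 1, sort))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}
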