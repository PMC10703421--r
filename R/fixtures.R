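#' Deterministic test states
#'
#' Hand-placed states for unit testing and examples:
#' * `chain` — `size` particles in a line at contact spacing, connected
#'   consecutively.
#' * `star` — one hub bonded to `size - 1` leaves.
#' * `two_clusters` — 6 marked particles as two 3-particle chains in
#'   separate networks (`size` is ignored).
#' * `free_particle` — a single unbonded particle at the box center.
#'
#' @param kind `"chain"`, `"star"`, `"two_clusters"` or `"free_particle"`.
#' @param size Number of particles (where applicable).
#' @param params A [sim_params()] supplying box geometry.
#' @return A [sim_state()].
#' @export
make_fixture <- function(kind = c("chain", "star", "two_clusters",
                                  "free_particle"),
                         size = NULL, params = sim_params()) {
  kind <- match.arg(kind)
  L <- params$box_side
  spacing <- 1.9 * params$particle_radius  # just inside contact range
  place <- function(pos, marked, edges) {
    sim_state(pos %% L, marked, edges, box_side = L,
              particle_radius = params$particle_radius, time = 0)
  }
  switch(kind,
    chain = {
      if (is.null(size) || size < 2) stop("chain needs size >= 2")
      pos <- cbind(spacing * (seq_len(size) - 1), L / 2)
      edges <- cbind(seq_len(size - 1), 2:size)
      place(pos, rep(FALSE, size), edges)
    },
    star = {
      if (is.null(size) || size < 3) stop("star needs size >= 3")
      ang <- 2 * pi * seq_len(size - 1) / (size - 1)
      pos <- rbind(c(L / 2, L / 2),
                   cbind(L / 2 + spacing * cos(ang),
                         L / 2 + spacing * sin(ang)))
      edges <- cbind(1L, 2:size)
      place(pos, rep(FALSE, size), edges)
    },
    two_clusters = {
      if (!is.null(size) && size != 6) stop("two_clusters has fixed size 6")
      pos <- rbind(cbind(spacing * (0:2) + 0.5, 1),
                   cbind(spacing * (0:2) + 0.5, 3))
      edges <- rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L))
      place(pos, rep(TRUE, 6), edges)
    },
    free_particle = {
      if (!is.null(size) && size != 1) stop("free_particle has fixed size 1")
      place(matrix(c(L / 2, L / 2), ncol = 2), FALSE,
            matrix(integer(0), ncol = 2))
    })
}
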