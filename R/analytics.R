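#' Number of DUMP clusters in a state
#'
#' A DUMP cluster is a connected component of the subgraph induced by the
#' marked particles (marked-marked forest edges only).
#'
#' @param state A [sim_state()].
#' @return Integer cluster count (0 if nothing is marked).
#' @export
count_dump_clusters <- function(state) {
  idx <- which(state$marked)
  if (length(idx) == 0) return(0L)
  e <- state$edges
  keep <- e[state$marked[e[, 1]] & state$marked[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(keep[, 1]),
               to = as.character(keep[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(idx)))
  as.integer(igraph::components(g)$no)
}

#' DUMP cluster count over the course of a run
#'
#' @param record A [run_simulation()] record.
#' @param cadence Sampling interval, s.
#' @return `data.frame` with `time_s` and `n_clusters`.
#' @export
dump_cluster_series <- function(record, cadence = 60) {
  times <- seq(record$seed_time, record$final_state$time, by = cadence)
  data.frame(
    time_s = times,
    n_clusters = vapply(times, function(t)
      as.integer(count_dump_clusters(state_at(record, t))), integer(1)))
}

#' Bootstrap estimate of a binary-outcome probability
#'
#' The point estimate is the fraction of `TRUE` outcomes; `iterations`
#' resamples of the full sample size, drawn with replacement, give the
#' resampling distribution and its 2.5-97.5 percentile interval.
#'
#' @param outcomes Logical vector of per-run outcomes.
#' @param iterations Number of bootstrap resamples.
#' @param seed Optional seed for the resampling stream.
#' @return Object of class `bootstrap_result` with `point_estimate`,
#'   `resample_estimates`, `iterations`, `sample_size` and `interval`.
#' @export
bootstrap_probability <- function(outcomes, iterations = 1000, seed = NULL) {
  if (length(outcomes) == 0) stop("outcomes must be non-empty")
  outcomes <- as.logical(outcomes)
  stopifnot(!anyNA(outcomes), iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(outcomes)
  res <- vapply(seq_len(iterations), function(i)
    mean(outcomes[sample.int(n, n, replace = TRUE)]), numeric(1))
  structure(list(point_estimate = mean(outcomes), resample_estimates = res,
                 iterations = iterations, sample_size = n,
                 interval = stats::quantile(res, c(0.025, 0.975),
                                            names = FALSE)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> p = %.3f (boot mean %.3f, 95%% interval %.3f-%.3f, n = %d, B = %d)\n",
    x$point_estimate, mean(x$resample_estimates), x$interval[1],
    x$interval[2], x$sample_size, x$iterations))
  invisible(x)
}

#' Unwrap a periodic trajectory
#'
#' Accumulates minimum-image per-frame displacements so the track lives in
#' unbounded coordinates; unambiguous because per-step displacements are
#' far below half the box side.
#'
#' @param xy T x 2 matrix of wrapped positions.
#' @param box_side Side length of the periodic box, um.
#' @return T x 2 matrix of unwrapped positions starting at the first frame.
#' @export
unwrap_track <- function(xy, box_side) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(xy)
  d <- diff(xy)
  d <- d - box_side * round(d / box_side)
  rbind(xy[1, , drop = FALSE],
        sweep(apply(d, 2, cumsum), 2, xy[1, ], `+`))
}

#' Mean squared displacement and diffusion-coefficient fit
#'
#' MSD at lag t is the mean over tracks of the squared displacement from
#' each track's first frame (the reference-point convention, not a
#' time-average).  The slope of a straight line through the origin is
#' fitted; `slope` follows the convention MSD = D t, while for 2D Brownian
#' motion MSD = 4 D t, so the physical coefficient is `diffusion_2d =
#' slope / 4`.  A log-log anomalous exponent is reported as a linearity
#' diagnostic (about 1 for diffusive motion, about 2 for ballistic).
#'
#' @param tracks List of T x 2 position matrices sampled at a uniform
#'   interval, each free of fission/fusion for its duration and already
#'   unwrapped (see [unwrap_track()]).
#' @param dt Sampling interval of the tracks, s.
#' @return Object of class `msd_curve`: `lags` (s), `msd` (um^2),
#'   `trajectory_count`, `slope` (um^2/s), `diffusion_2d` (um^2/s),
#'   `anomalous_exponent`.
#' @export
msd_and_diffusion <- function(tracks, dt) {
  stopifnot(is.list(tracks), dt > 0)
  tracks <- Filter(function(x) nrow(x) >= 2, lapply(tracks, as.matrix))
  if (length(tracks) == 0)
    stop("no track has at least 2 frames")
  max_lag <- max(vapply(tracks, nrow, integer(1))) - 1L
  msd <- numeric(max_lag)
  cnt <- integer(max_lag)
  for (tr in tracks) {
    nlag <- nrow(tr) - 1L
    disp2 <- (tr[-1, 1] - tr[1, 1])^2 + (tr[-1, 2] - tr[1, 2])^2
    msd[seq_len(nlag)] <- msd[seq_len(nlag)] + disp2
    cnt[seq_len(nlag)] <- cnt[seq_len(nlag)] + 1L
  }
  msd <- msd / cnt
  lags <- seq_len(max_lag) * dt
  slope <- sum(lags * msd) / sum(lags^2)
  pos <- msd > 0
  alpha <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(msd[pos]) ~ log(lags[pos])))[2])
  else NA_real_
  structure(list(lags = c(0, lags), msd = c(0, msd),
                 trajectory_count = c(length(tracks), cnt),
                 slope = slope, diffusion_2d = slope / 4,
                 anomalous_exponent = alpha),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf(
    "<msd_curve> %d lags, slope = %.4g um^2/s (2D D = %.4g), exponent %.2f\n",
    length(x$lags) - 1L, x$slope, x$diffusion_2d, x$anomalous_exponent))
  invisible(x)
}

# component (by membership before the event) containing particle `a` at the
# moment just before event row `k` of the record
component_before_event <- function(record, k) {
  ev <- record$events
  t_ev <- ev$time_s[k]
  edges <- list()
  for (j in seq_len(k - 1)) {
    a <- ev$particle_a[j]; b <- ev$particle_b[j]
    if (ev$event_type[j] == "fusion") {
      edges[[length(edges) + 1L]] <- c(a, b)
    } else {
      hit <- which(vapply(edges, function(e)
        (e[1] == a && e[2] == b) || (e[1] == b && e[2] == a), logical(1)))
      edges[[hit[1]]] <- NULL
    }
  }
  n <- record$params$n_total
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  seen <- rep(FALSE, n)
  q <- ev$particle_a[k]
  seen[q] <- TRUE
  head <- 1L
  while (head <= length(q)) {
    u <- q[head]; head <- head + 1L
    for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; q <- c(q, v) }
  }
  sort(q)
}

#' Event counts at experimental imaging resolution
#'
#' Restricts the event log to the final `window` seconds, assigns each
#' event to its nearest `frame`-second imaging frame, and collapses
#' multiple events of one type on the same network lineage within a frame
#' to a single observable event, emulating what frame-rate-limited imaging
#' can resolve.
#'
#' @param record A [run_simulation()] record with events.
#' @param frame Imaging frame interval, s.
#' @param window Analysis window at the end of the run, s.
#' @return Named list `fission_count`, `fusion_count`.
#' @export
event_rates_at_experimental_resolution <- function(record, frame = 10,
                                                   window = 300) {
  t_end <- record$final_state$time
  if (t_end < window)
    stop("record (", t_end, " s) is shorter than the analysis window (",
         window, " s)")
  ev <- record$events
  in_win <- which(ev$time_s > t_end - window & ev$time_s <= t_end)
  if (length(in_win) == 0)
    return(list(fission_count = 0L, fusion_count = 0L))
  keys <- vapply(in_win, function(k) {
    lineage <- min(component_before_event(record, k))
    fr <- floor(ev$time_s[k] / frame + 0.5)
    paste(fr, ev$event_type[k], lineage, sep = "|")
  }, character(1))
  types <- ev$event_type[in_win][!duplicated(keys)]
  list(fission_count = sum(types == "fission"),
       fusion_count = sum(types == "fusion"))
}

#' Freedman-Diaconis histogram bin edges
#'
#' Bin width `2 * IQR * n^(-1/3)`; edges span the data range.  With zero
#' IQR the square-root rule is used instead so degenerate data still bin;
#' a constant vector gets one unit-width bin around the value.
#'
#' @param values Numeric vector (at least 2 finite values).
#' @return Numeric vector of bin edges.
#' @export
fd_bin_edges <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  rng <- range(values)
  iqr <- stats::IQR(values)
  if (iqr > 0) {
    width <- 2 * iqr * length(values)^(-1 / 3)
    nb <- max(1L, ceiling((rng[2] - rng[1]) / width))
  } else {
    if (rng[1] == rng[2]) return(rng[1] + c(-0.5, 0.5))
    nb <- max(1L, ceiling(sqrt(length(values))))
    width <- (rng[2] - rng[1]) / nb
  }
  rng[1] + (0:nb) * width
}

#' Time for two aggregates to meet by 1D matrix diffusion
#'
#' For two aggregates a distance x apart diffusing with coefficient D
#' inside a continuous mitochondrial matrix, the characteristic meeting
#' time by one-dimensional diffusion is `x^2 / (2 D)`.
#'
#' @param distance Separation, um.
#' @param D Diffusion coefficient, um^2/s.
#' @return Time, seconds.
#' @examples
#' diffusion_meeting_time(1.64, 1e-4) / 3600  # about 3.7 hours
#' @export
diffusion_meeting_time <- function(distance, D) {
  stopifnot(distance >= 0)
  if (!is.numeric(D) || D <= 0) stop("D must be positive")
  distance^2 / (2 * D)
}

#' Mean distance of points to their centroid
#'
#' @param points Matrix of positions (rows = points, 2 or 3 columns).
#' @return Mean Euclidean distance to the coordinate-mean centroid, um.
#' @export
mean_distance_to_centroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("need at least one point")
  centroid <- colMeans(points)
  mean(sqrt(rowSums(sweep(points, 2, centroid)^2)))
}

#' Sweep the biased-fission fraction
#'
#' For each fraction, runs `n_reps` independent simulations under the
#' aggregate-expression laws with that fraction of fission events biased,
#' evaluates terminal inheritance, and bootstraps the DUMP-inheritance
#' probability.
#'
#' @param params A [sim_params()].
#' @param fractions Numeric vector of biased fractions in `[0, 1]`.
#' @param n_reps Replicate runs per fraction (>= 2).
#' @param seeding A [seeding_spec()].
#' @param base_seed Integer; run r of fraction f uses seed
#'   `base_seed + (f_index - 1) * n_reps + r - 1`.
#' @param iterations Bootstrap iterations per fraction.
#' @return `data.frame` with one row per fraction: `fraction`,
#'   `p_inherit`, `boot_mean`, `ci_lower`, `ci_upper`, `n_runs`; the full
#'   [bootstrap_probability()] objects are attached as
#'   `attr(result, "bootstrap")`.
#' @export
bias_sweep <- function(params, fractions, n_reps, seeding = seeding_spec(),
                       base_seed = 1, iterations = 1000) {
  stopifnot(n_reps >= 2, all(fractions >= 0), all(fractions <= 1))
  boots <- vector("list", length(fractions))
  rows <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    config <- sim_config("mitofluc", "mitofluc",
                         bias = bias_config(if (f > 0) "biased" else "random",
                                            f))
    outcomes <- vapply(seq_len(n_reps), function(r) {
      rec <- run_simulation(params, config, seeding,
                            seed = base_seed + (fi - 1L) * n_reps + r - 1L,
                            snapshot_dt = NA, record_events = FALSE)
      evaluate_inheritance(rec$final_state, params$n_inherit)$contains_dump
    }, logical(1))
    bt <- bootstrap_probability(outcomes, iterations = iterations)
    boots[[fi]] <- bt
    rows[[fi]] <- data.frame(
      fraction = f, p_inherit = bt$point_estimate,
      boot_mean = mean(bt$resample_estimates),
      ci_lower = bt$interval[1], ci_upper = bt$interval[2],
      n_runs = as.integer(n_reps))
  }
  out <- do.call(rbind, rows)
  attr(out, "bootstrap") <- boots
  out
}

#' Network volumes of a state
#'
#' 3D-equivalent volume of every network: particle count times the unit
#' mitochondrion volume.
#'
#' @param state A [sim_state()].
#' @param params A [sim_params()].
#' @return Numeric vector, um^3, one entry per network.
#' @export
network_volumes <- function(state, params) {
  as.numeric(table(component_membership(state))) * params$unit_mito_volume
}

#' Quantile-quantile comparison of two volume samples
#'
#' Matches the quantiles of both samples on the probability grid of the
#' smaller sample and fits a least-squares line; identical distributions
#' give slope 1, intercept 0.
#'
#' @param sample_a,sample_b Numeric vectors (e.g. experimental and
#'   simulated network volumes).
#' @return List with `quantiles` (`data.frame` of matched pairs), `slope`,
#'   `intercept`, `r_squared` and `residuals`.
#' @export
volume_qq <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  n <- min(length(sample_a), length(sample_b))
  p <- stats::ppoints(n)
  qa <- stats::quantile(sample_a, p, names = FALSE)
  qb <- stats::quantile(sample_b, p, names = FALSE)
  fit <- stats::lm(qb ~ qa)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((qb - mean(qb))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  list(quantiles = data.frame(q_a = qa, q_b = qb),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       residuals = res)
}
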