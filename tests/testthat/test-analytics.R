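test_that("DUMP clusters are components of the marked subgraph", {
  expect_identical(count_dump_clusters(make_fixture("two_clusters")), 2L)
  one_run <- marked_chain(rep(TRUE, 6))
  expect_identical(count_dump_clusters(one_run), 1L)
  expect_identical(count_dump_clusters(make_fixture("chain", 4)), 0L)
  # marked chain A-B plus a marked singleton C elsewhere: 2 clusters
  st <- hand_state(matrix(runif(10, 0, 8), ncol = 2),
                   edges = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)),
                   marked = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(count_dump_clusters(st), 2L)
  # six pairwise non-adjacent marked singletons
  st6 <- hand_state(matrix(runif(12, 0, 8), ncol = 2),
                    marked = rep(TRUE, 6))
  expect_identical(count_dump_clusters(st6), 6L)
})

test_that("bootstrap probability reproduces the point estimate and converges", {
  all_true <- rep(TRUE, 25)
  b <- bootstrap_probability(all_true, seed = 1)
  expect_equal(b$point_estimate, 1)
  expect_equal(unname(diff(b$interval)), 0)

  out <- c(rep(TRUE, 3), rep(FALSE, 17))
  b2 <- bootstrap_probability(out, seed = 2)
  expect_equal(b2$point_estimate, 0.15)
  expect_true(all(b2$resample_estimates >= 0 & b2$resample_estimates <= 1))
  expect_lte(b2$interval[1], b2$point_estimate)
  expect_gte(b2$interval[2], b2$point_estimate)

  # law of large numbers: resample mean near the point estimate
  b3 <- bootstrap_probability(out, iterations = 10000, seed = 3)
  mc_se <- stats::sd(b3$resample_estimates) / sqrt(b3$iterations)
  expect_lt(abs(mean(b3$resample_estimates) - b3$point_estimate), 3 * mc_se)
  expect_error(bootstrap_probability(logical(0)))
})

test_that("track unwrapping undoes periodic wrapping of small displacements", {
  L <- 8.31
  true_path <- cbind(cumsum(c(8.2, rep(0.3, 10))), rep(1, 11))
  wrapped <- cbind(true_path[, 1] %% L, true_path[, 2])
  un <- unwrap_track(wrapped, L)
  expect_equal(diff(un[, 1]), diff(true_path[, 1]), tolerance = 1e-12)
})

test_that("MSD of engine free-particle tracks recovers the configured D", {
  p <- default_params
  d_wt <- eval_rate(p$profiles$wt$diffusion_law, 1, p$unit_mito_volume)
  set.seed(19)
  n_tracks <- 1000
  n_steps <- 30
  tracks <- lapply(seq_len(n_tracks), function(i) {
    st <- make_fixture("free_particle", params = p)
    xs <- matrix(NA_real_, n_steps + 1, 2)
    xs[1, ] <- st$pos
    for (k in seq_len(n_steps)) {
      st <- diffuse(st, p)
      xs[k + 1, ] <- st$pos
    }
    unwrap_track(xs, p$box_side)
  })
  curve <- msd_and_diffusion(tracks, dt = p$dt_sim)
  # group-wise slope spread gives the Monte Carlo standard error
  groups <- split(tracks, rep(1:10, each = n_tracks / 10))
  slopes <- vapply(groups, function(g)
    msd_and_diffusion(g, dt = p$dt_sim)$slope, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(curve$slope - 4 * d_wt), 3 * se)
  expect_equal(curve$diffusion_2d, curve$slope / 4)
  expect_equal(curve$msd[1], 0)
  expect_true(all(diff(curve$trajectory_count) <= 0))
})

test_that("degenerate tracks give zero slope or a ballistic diagnostic", {
  still <- list(matrix(1, 10, 2))
  curve <- msd_and_diffusion(still, dt = 0.1)
  expect_equal(curve$slope, 0)
  expect_true(all(curve$msd == 0))

  ballistic <- list(cbind(0.05 * (0:100), 0))
  bc <- msd_and_diffusion(ballistic, dt = 0.1)
  expect_gt(bc$anomalous_exponent, 1.8)  # flagged as non-diffusive
  expect_error(msd_and_diffusion(list(matrix(1, 1, 2)), dt = 0.1))
})

test_that("event downsampling collapses same-lineage same-frame events", {
  p <- sim_params(t_equil = 600, t_eval = 60)
  rec <- run_simulation(p, sim_config(), seeding_spec(cluster_count = 1),
                        seed = 2)
  # synthetic event log on a record shell: a 4-chain formed by fusions,
  # then three fissions at 6901.2 s, 6901.9 s, 6905.0 s
  rec$events <- data.frame(
    time_s = c(10, 20, 30, 6901.2, 6901.9, 6905.0),
    event_type = c("fusion", "fusion", "fusion",
                   "fission", "fission", "fission"),
    particle_a = c(1, 2, 3, 3, 2, 1),
    particle_b = c(2, 3, 4, 4, 3, 2),
    comp_size_before = c(NA, NA, NA, 4, 3, 2),
    comp_size_after_a = c(2, 3, 4, 3, 2, 1),
    comp_size_after_b = c(2, 3, 4, 1, 1, 1),
    comp_has_dump = 0)
  rec$final_state$time <- 7200
  er <- event_rates_at_experimental_resolution(rec)
  # 6901.2 and 6901.9 share frame 690 and lineage {min id 1};
  # 6905.0 rounds to frame 691: two observable fissions
  expect_identical(er$fission_count, 2L)
  expect_identical(er$fusion_count, 0L)

  # fission and fusion of disjoint components in one frame both count
  rec$events <- data.frame(
    time_s = c(10, 20, 7105, 7106),
    event_type = c("fusion", "fusion", "fission", "fusion"),
    particle_a = c(1, 3, 1, 5), particle_b = c(2, 4, 2, 6),
    comp_size_before = c(NA, NA, 2, NA),
    comp_size_after_a = c(2, 2, 1, 2),
    comp_size_after_b = c(2, 2, 1, 2), comp_has_dump = 0)
  er2 <- event_rates_at_experimental_resolution(rec)
  expect_identical(er2$fission_count, 1L)
  expect_identical(er2$fusion_count, 1L)

  rec$events <- rec$events[0, ]
  er3 <- event_rates_at_experimental_resolution(rec)
  expect_identical(c(er3$fission_count, er3$fusion_count), c(0L, 0L))
  rec$final_state$time <- 100
  expect_error(event_rates_at_experimental_resolution(rec), "window")
})

test_that("Freedman-Diaconis binning follows the rule with a degenerate fallback", {
  x <- c(0, 1, 3, 4, 5, 7, 8, 8)  # n = 8
  width <- 2 * stats::IQR(x) * 8^(-1 / 3)
  edges <- fd_bin_edges(x)
  expect_equal(diff(edges)[1], width)
  expect_lte(edges[1], min(x))
  expect_gte(edges[length(edges)], max(x))

  set.seed(5)
  u <- runif(1000)
  w <- diff(fd_bin_edges(u))[1]
  expect_equal(w, 2 * stats::IQR(u) * 1000^(-1 / 3), tolerance = 1e-12)
  expect_lt(abs(w - 0.1), 0.02)

  expect_identical(fd_bin_edges(rep(2, 10)), c(1.5, 2.5))
  skew <- c(rep(1, 50), 1, 9)   # zero IQR, non-zero range
  expect_identical(length(fd_bin_edges(skew)) - 1L,
                   as.integer(ceiling(sqrt(52))))
  expect_error(fd_bin_edges(3))
})

test_that("matrix-diffusion meeting time follows x^2 / (2D)", {
  expect_equal(diffusion_meeting_time(1.64, 1e-4), 1.64^2 / 2e-4)
  expect_equal(diffusion_meeting_time(1.64, 1e-4) / 3600, 3.7,
               tolerance = 0.01)
  expect_equal(diffusion_meeting_time(0, 5), 0)
  expect_equal(diffusion_meeting_time(2, 0.5), 4)
  expect_error(diffusion_meeting_time(1, 0))
})

test_that("mean distance to centroid handles the standard geometries", {
  expect_equal(mean_distance_to_centroid(rbind(c(0, 0), c(2, 0))), 1)
  expect_equal(mean_distance_to_centroid(rbind(c(3, 7))), 0)
  square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(mean_distance_to_centroid(square), sqrt(2) / 2)
  expect_equal(mean_distance_to_centroid(rbind(c(0, 0, 0), c(0, 0, 2))), 1)
  expect_error(mean_distance_to_centroid(matrix(0, 0, 2)))
})

test_that("quantile-quantile comparison recovers identity and scaling", {
  set.seed(31)
  a <- rexp(400)
  qq <- volume_qq(a, a)
  expect_equal(qq$slope, 1, tolerance = 1e-9)
  expect_equal(qq$intercept, 0, tolerance = 1e-9)
  expect_equal(qq$r_squared, 1, tolerance = 1e-9)

  qq2 <- volume_qq(a, 2 * a)
  expect_equal(qq2$slope, 2, tolerance = 1e-9)

  b <- runif(500); c2 <- runif(500)
  qq3 <- volume_qq(b, c2)
  expect_gt(qq3$slope, 0.85)
  expect_lt(qq3$slope, 1.15)
})

test_that("a smoke-scale bias sweep returns one bootstrapped row per fraction", {
  p <- sim_params(t_equil = 600, t_eval = 240)
  sw <- bias_sweep(p, fractions = c(0, 1), n_reps = 3,
                   seeding = seeding_spec(cluster_count = 1), base_seed = 50,
                   iterations = 200)
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$n_runs, c(3L, 3L))
  expect_true(all(sw$p_inherit >= 0 & sw$p_inherit <= 1))
  expect_identical(length(attr(sw, "bootstrap")), 2L)
})
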