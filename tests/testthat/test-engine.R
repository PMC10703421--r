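test_that("initialization seeds singleton particles uniformly and reproducibly", {
  p <- default_params
  s1 <- initialize_state(p, seed = 1)
  expect_identical(nrow(s1$pos), 54L)
  expect_identical(nrow(s1$edges), 0L)
  expect_identical(length(unique(component_membership(s1))), 54L)
  expect_false(any(s1$marked))
  expect_true(all(s1$pos >= 0 & s1$pos < p$box_side))
  s2 <- initialize_state(p, seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1$pos, initialize_state(p, seed = 2)$pos))
})

test_that("a free particle moves exactly one step length per diffusion step", {
  p <- default_params
  st <- make_fixture("free_particle", params = p)
  d_wt <- eval_rate(p$profiles$wt$diffusion_law, 1, p$unit_mito_volume)
  expect_equal(d_wt, 9.4532e-4, tolerance = 1e-6)
  set.seed(3)
  for (i in 1:20) {
    st2 <- diffuse(st, p)
    expect_equal(min_image_distance_between(st, st2, p$box_side),
                 sqrt(4 * d_wt * p$dt_sim), tolerance = 1e-12)
    st <- st2
  }
})

test_that("a zero-diffusion law leaves positions unchanged (up to the floor)", {
  p <- sim_params(profiles = within_profile_diffusion_zero())
  st <- make_fixture("chain", 4, p)
  st2 <- diffuse(st, p)
  expect_equal(st2$pos, st$pos, tolerance = 1e-5)
})

test_that("networks translate as rigid bodies with wrapped coordinates", {
  p <- default_params
  st <- make_fixture("chain", 5, p)
  d0 <- pairwise_mi(st)
  set.seed(11)
  for (i in 1:50) st <- diffuse(st, p)
  expect_true(all(st$pos >= 0 & st$pos < p$box_side))
  expect_equal(pairwise_mi(st), d0, tolerance = 1e-9)
})

test_that("fusion requires contact, joins closest pairs, and preserves the forest", {
  p <- default_params
  r <- p$particle_radius
  far <- hand_state(rbind(c(1, 1), c(1 + 3 * r, 1)))
  set.seed(5)
  far2 <- attempt_fusions(far, p, force_prob = 1)
  expect_identical(nrow(far2$edges), 0L)

  near <- hand_state(rbind(c(1, 1), c(1 + 1.5 * r, 1)))
  near2 <- attempt_fusions(near, p, force_prob = 1)
  expect_identical(nrow(near2$edges), 1L)
  expect_identical(length(unique(component_membership(near2))), 1L)

  # three mutually-in-contact singletons: always one network of 3, 2 edges
  for (i in 1:50) {
    tri <- hand_state(rbind(c(1, 1), c(1 + 1.5 * r, 1),
                            c(1 + 0.75 * r, 1 + 1.2 * r)))
    tri2 <- attempt_fusions(tri, p, force_prob = 1)
    expect_identical(nrow(tri2$edges), 2L)
    expect_identical(length(unique(component_membership(tri2))), 1L)
    validate_state(tri2)
  }
})

test_that("contact detection uses the minimum image across the boundary", {
  p <- default_params
  L <- p$box_side
  r <- p$particle_radius
  st <- hand_state(rbind(c(0.01, 2), c(L - 0.01, 2)))  # touching across wrap
  expect_lt(min_image_distance(st, 1, 2), 2 * r)
  set.seed(8)
  st2 <- attempt_fusions(st, p, force_prob = 1)
  expect_identical(nrow(st2$edges), 1L)
})

test_that("biased fission cuts the aggregate boundary; adjacent mode cuts one hop out", {
  p <- default_params
  # chain A(marked)-B-C
  st <- marked_chain(c(TRUE, FALSE, FALSE))
  set.seed(2)
  b <- attempt_fissions(st, p, bias = bias_config("biased", 1),
                        force_prob = 1)
  expect_identical(sort_edges(b$edges), rbind(c(2L, 3L)))
  memb <- component_membership(b)
  expect_identical(length(unique(memb)), 2L)
  expect_true(memb[1] != memb[2])  # components {A}, {B, C}

  a <- attempt_fissions(st, p, bias = bias_config("adjacent", 1),
                        force_prob = 1)
  expect_identical(sort_edges(a$edges), rbind(c(1L, 2L)))
  memb <- component_membership(a)
  expect_true(memb[1] == memb[2] && memb[2] != memb[3])  # {A, B}, {C}
})

test_that("an unmarked network under biased mode falls back to a uniform cut", {
  p <- default_params
  st <- make_fixture("chain", 4, p)
  set.seed(4)
  cuts <- replicate(60, {
    st2 <- attempt_fissions(st, p, bias = bias_config("biased", 1),
                            force_prob = 1)
    nrow(st2$edges)
  })
  expect_true(all(cuts == 2L))  # fission always fires via the fallback
})

test_that("a fully marked network under biased mode skips fission, keeping clusters whole", {
  p <- default_params
  st <- marked_chain(c(TRUE, TRUE, TRUE))
  set.seed(4)
  st2 <- attempt_fissions(st, p, bias = bias_config("biased", 1),
                          force_prob = 1)
  expect_identical(nrow(st2$edges), 2L)  # no cut happened
  expect_identical(count_dump_clusters(st2), 1L)
})

test_that("clustered seeding realizes the requested cluster structure", {
  p <- default_params
  set.seed(21)
  rec <- run_simulation(p, sim_config("wt", "wt", bias_config("random", 0)),
                        seeding_spec(cluster_count = 1), seed = 301,
                        snapshot_dt = NA, record_events = FALSE)
  st <- state_at(rec, p$t_equil)
  expect_identical(sum(st$marked), 6L)
  expect_identical(count_dump_clusters(st), 1L)

  # singlets and clustered-with-6-clusters are equivalent: 6 isolated marks
  for (spec in list(seeding_spec("singlets"),
                    seeding_spec(cluster_count = 6))) {
    rec <- run_simulation(p, sim_config(), spec, seed = 302,
                          snapshot_dt = NA, record_events = FALSE)
    st <- state_at(rec, p$t_equil)
    expect_identical(sum(st$marked), 6L)
    expect_identical(count_dump_clusters(st), 6L)
    marked <- which(st$marked)
    for (k in seq_len(nrow(st$edges)))
      expect_false(all(st$edges[k, ] %in% marked))
  }
})

test_that("seeding errors out when the state cannot host the requested clusters", {
  p <- default_params
  st <- make_fixture("chain", 3, p)  # only 3 particles for 6 marks
  expect_error(seed_dumps(st, seeding_spec(cluster_count = 1), p,
                          max_tries = 50),
               "seeding failed|exceeds")
})

test_that("full runs are deterministic and conserve particles, marks and the forest", {
  p <- sim_params(t_equil = 300, t_eval = 300)
  cfg <- sim_config()
  r1 <- run_simulation(p, cfg, seeding_spec(cluster_count = 2), seed = 7)
  r2 <- run_simulation(p, cfg, seeding_spec(cluster_count = 2), seed = 7)
  expect_identical(r1, r2)

  snaps <- r1$snapshots
  for (t in unique(snaps$time_s)) {
    st <- state_at(r1, t)
    expect_identical(nrow(st$pos), 54L)       # particle conservation
    validate_state(st)                        # forest invariant
    n_marked <- sum(st$marked)
    expect_identical(n_marked, if (t < p$t_equil) 0L else 6L)
  }
  # event log consistency: fissions remove existing edges, fusions join
  # distinct components (implied by successful replay into valid forests)
  expect_true(all(r1$events$event_type %in% c("fission", "fusion")))
  expect_true(!is.unsorted(r1$events$time_s))
})

test_that("a run with t_eval = 0 stops at the seeding snapshot", {
  p <- sim_params(t_equil = 120, t_eval = 0)
  rec <- run_simulation(p, sim_config(), seeding_spec(cluster_count = 1),
                        seed = 5)
  expect_equal(rec$final_state$time, 120)
  expect_identical(sum(rec$final_state$marked), 6L)
})

test_that("marked cluster count never increases under fully biased fission", {
  p <- sim_params(t_equil = 600, t_eval = 1200)
  cfg <- sim_config("mitofluc", "mitofluc", bias_config("biased", 1))
  for (s in 1:5) {
    rec <- run_simulation(p, cfg, seeding_spec("singlets"), seed = 400 + s)
    series <- dump_cluster_series(rec, cadence = 60)
    expect_true(all(diff(series$n_clusters) <= 0))
  }
})
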