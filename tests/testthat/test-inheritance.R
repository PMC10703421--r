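test_that("the largest network is selected, with uniform random tie-breaking", {
  p <- default_params
  comp_sizes <- function(st) as.numeric(table(component_membership(st)))
  # sizes {3, 2, 1}: the chain of 3 must always win
  st <- hand_state(matrix(runif(12, 0, 8), ncol = 2),
                   edges = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)))
  set.seed(1)
  for (i in 1:10) expect_setequal(largest_component(st), 1:3)

  # two components of 3: each should win about half the time
  st2 <- hand_state(matrix(runif(12, 0, 8), ncol = 2),
                    edges = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L)))
  set.seed(42)
  wins <- replicate(4000, 1 %in% largest_component(st2))
  expect_gt(mean(wins), 0.45)
  expect_lt(mean(wins), 0.55)
})

test_that("the branch tip is always an endpoint of a true diameter path", {
  # brute-force oracle (igraph all-pairs distances) on random trees up to 54
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:54, 1)
    st <- tree_state(random_tree_edges(n), n)
    members <- seq_len(n)
    tip <- longest_branch_tip(st, members)
    expect_true(tip %in% members)
    expect_identical(oracle_ecc(st, members, tip), oracle_diameter(st, members))
  }
})

test_that("known small trees give the expected tips and diameters", {
  p5 <- make_fixture("chain", 5)
  set.seed(3)
  for (i in 1:10) expect_true(longest_branch_tip(p5, 1:5) %in% c(1L, 5L))
  star <- make_fixture("star", 5)
  for (i in 1:10) expect_true(longest_branch_tip(star, 1:5) %in% 2:5)
  # caterpillar: spine 1-2-3-4-5 with a leaf 6 on 3; diameter ends are 1 or 5
  cat6 <- tree_state(rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L),
                           c(3L, 6L)), 6)
  for (i in 1:20) expect_true(longest_branch_tip(cat6, 1:6) %in% c(1L, 5L))
})

test_that("breadth-first selection from the tip matches the path-prefix oracle", {
  chain <- make_fixture("chain", 20)
  set.seed(9)
  sel <- select_inherited(chain, tip = 1L, n_inherit = 15)
  expect_identical(sort(sel), 1:15)                     # path prefix
  sel_rev <- select_inherited(chain, tip = 20L, n_inherit = 15)
  expect_identical(sort(sel_rev), 6:20)
  expect_identical(select_inherited(chain, 1L, 0), integer(0))
  # a component smaller than the quota is inherited whole
  chain8 <- make_fixture("chain", 8)
  expect_identical(sort(select_inherited(chain8, 1L, 15)), 1:8)
  # selection sizes on random trees: min(n_inherit, component size)
  for (rep in 1:20) {
    n <- sample(2:54, 1)
    st <- tree_state(random_tree_edges(n), n)
    k <- sample(0:20, 1)
    sel <- select_inherited(st, sample(n, 1), k)
    expect_identical(length(sel), min(k, n))
    expect_identical(anyDuplicated(sel), 0L)
  }
})

test_that("inheritance evaluation composes the two steps without mutating the state", {
  p <- default_params
  chain <- marked_chain(c(rep(FALSE, 14), rep(TRUE, 6)))  # marks at far end
  before <- chain
  set.seed(13)
  res <- evaluate_inheritance(chain, 15)
  expect_identical(chain, before)                       # non-mutation
  expect_identical(res$largest_component_size, 20L)
  expect_identical(res$inherited_count, 15L)
  # tip is node 1 or 20; marks occupy 15:20, which overlaps any 15-prefix
  expect_true(res$contains_dump)

  # marks confined to the last 5 of a 20-chain: only the far tip avoids them
  chain2 <- marked_chain(c(rep(FALSE, 15), rep(TRUE, 5)))
  hits <- replicate(200, {
    r <- evaluate_inheritance(chain2, 15)
    r$contains_dump
  })
  # tip 1 -> particles 1..15, no mark; tip 20 -> 6..20, marked
  expect_setequal(unique(hits), c(TRUE, FALSE))

  unmarked <- make_fixture("chain", 10)
  expect_false(evaluate_inheritance(unmarked, 15)$contains_dump)
})

test_that("enumerating cluster placements on a chain matches the BFS overlap rule", {
  # 6-mark cluster at offset o on a 20-chain is inherited from tip 1
  # iff the cluster starts within the first 15 nodes
  for (o in c(1, 5, 10, 15, 16)) {
    marks <- rep(FALSE, 20)
    marks[o:min(20, o + 5)] <- TRUE
    st <- marked_chain(marks)
    sel <- select_inherited(st, tip = 1L, n_inherit = 15)
    expect_identical(any(st$marked[sel]), o <= 15)
  }
})

test_that("the inheritance timeseries covers seeding to the end at the cadence", {
  p <- sim_params(t_equil = 300, t_eval = 600)
  rec <- run_simulation(p, sim_config(), seeding_spec(cluster_count = 1),
                        seed = 11)
  ts <- inheritance_timeseries(rec, cadence = 60)
  expect_identical(nrow(ts), as.integer((300 + 600 - 300) / 60 + 1))
  expect_identical(ts$time_s, seq(300, 900, 60))
  expect_true(all(ts$inherited_count <= p$n_inherit))
  expect_true(all(ts$inherited_count ==
                    pmin(p$n_inherit, ts$largest_component_size)))
  ts2 <- inheritance_timeseries(rec, cadence = p$t_eval)
  expect_identical(nrow(ts2), 2L)
  expect_error(inheritance_timeseries(rec, cadence = 7),
               "cadence")
})
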