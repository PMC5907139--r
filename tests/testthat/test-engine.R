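test_that("synchronous stepping follows the hand-derived 4-state cycle", {
  net <- parse_rules(c("ERK* = not D", "D* = ERK"))
  # (1,1) -> (0,1) -> (0,0) -> (1,0) -> (1,1), by truth-table stepping
  path <- list(c(ERK = 1L, D = 1L), c(ERK = 0L, D = 1L),
               c(ERK = 0L, D = 0L), c(ERK = 1L, D = 0L),
               c(ERK = 1L, D = 1L))
  st <- path[[1]]
  for (i in 2:5) {
    st <- step_synchronous(net, st)
    expect_equal(st, path[[i]])
  }
})

test_that("negation flips and fixed points stay put", {
  net <- parse_rules("A* = not A")
  expect_equal(step_synchronous(net, c(A = 0L))[["A"]], 1L)
  idn <- parse_rules("A* = A")
  expect_equal(step_synchronous(idn, c(A = 1L)), c(A = 1L))
})

test_that("missing clamp for an input is an error", {
  net <- parse_rules(c("#input: In", "Out* = In"))
  expect_error(step_synchronous(net, c(In = 1L, Out = 0L)),
               "missing clamp for input node 'In'")
  expect_silent(step_synchronous(net, c(In = 1L, Out = 0L), c(In = 1)))
})

test_that("synchronous trajectories are deterministic and ignore the seed", {
  net <- negative_feedback_net()
  t1 <- simulate_network(net, n_steps = 12)
  t2 <- simulate_network(net, n_steps = 12, seed = 99)
  expect_identical(unclass(t1)[, ], unclass(t2)[, ])
  # DUSP5-type loop under a clamped basal drive: period-4 oscillation
  loop <- parse_rules(c("#input: Basal",
                        "ERK* = Basal and not DUSP5",
                        "DUSP5* = ERK",
                        "Basal = True", "ERK = True", "DUSP5 = False"))
  att <- find_attractor(loop)
  expect_equal(att$cycle_length, 4L)
  expect_equal(classify_node_pattern(att, "ERK"), "OSCILLATING")
  expect_equal(classify_node_pattern(att, "DUSP5"), "OSCILLATING")
})

test_that("asynchronous runs update one node at a time and reproduce bitwise", {
  net <- parse_rules(c("A* = not A", "B* = B", "A = False", "B = True"))
  t1 <- simulate_network(net, n_steps = 20, mode = "asynchronous", seed = 7)
  t2 <- simulate_network(net, n_steps = 20, mode = "asynchronous", seed = 7)
  expect_identical(unclass(t1)[, ], unclass(t2)[, ])
  flips <- rowSums(abs(diff(t(unclass(t1)[, ]))))
  expect_true(all(flips <= 1))        # at most one node changes per step
  expect_true(all(unclass(t1)["B", ] == 1))  # B* = B never flips
  expect_error(simulate_network(net, n_steps = 5, mode = "asynchronous"),
               "seed")
})

test_that("seeded async exploration visits exactly the exhaustively reachable states", {
  net <- parse_rules(c("ERK* = not D", "D* = ERK"))
  init <- c(ERK = 1L, D = 1L)
  oracle <- async_reachable(net, init)
  visited <- character(0)
  for (s in 1:40) {
    tr <- simulate_network(net, init = init, n_steps = 12,
                           mode = "asynchronous", seed = s)
    visited <- union(visited, apply(unclass(tr)[, ], 2, paste, collapse = ""))
  }
  expect_setequal(visited, oracle)
})

test_that("clamped inputs never change within a trajectory", {
  net <- parse_rules(c("#input: Herceptin",
                       "HER2* = not Herceptin",
                       "ERK* = HER2",
                       "HER2 = True", "ERK = True"))
  for (mode in c("synchronous", "asynchronous")) {
    tr <- simulate_network(net, clamps = c(Herceptin = 1), n_steps = 10,
                           mode = mode, seed = 3)
    expect_true(all(unclass(tr)["Herceptin", ] == 1))
  }
})

test_that("find_attractor matches the exhaustive transition-graph oracle on fixtures", {
  fixtures <- list(
    parse_rules("A* = A"),
    negative_feedback_net(),
    # 3-node chain with the source clamped OFF: everything drains to OFF
    parse_rules(c("#input: A", "B* = A", "C* = B",
                  "A = False", "B = True", "C = True")))
  expected_cycles <- c(1L, 4L, 1L)
  expected_transients_max <- c(0L, 0L, 3L)
  for (i in seq_along(fixtures)) {
    net <- fixtures[[i]]
    got <- find_attractor(net)
    ora <- exhaustive_attractor(net)
    expect_equal(got$cycle_length, ora$cycle_length)
    expect_equal(got$transient_length, ora$transient_length)
    expect_equal(got$cycle_length, expected_cycles[i])
    expect_lte(got$transient_length, expected_transients_max[i])
    # one synchronous step maps the last cycle state to the first
    last <- setNames(as.integer(got$cycle[, got$cycle_length]),
                     rownames(got$cycle))
    wrap <- step_synchronous(net, last,
                             duspboolnet:::check_clamps(net, NULL))
    expect_equal(unname(wrap[net$nodes]), unname(got$cycle[, 1]))
  }
})

test_that("find_attractor agrees with the oracle on many random networks", {
  set.seed(42)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    net <- parse_rules(random_network_text(k))
    got <- find_attractor(net)
    ora <- exhaustive_attractor(net)
    expect_equal(got$cycle_length, ora$cycle_length)
    expect_equal(got$transient_length, ora$transient_length)
  }
})

test_that("pattern classification covers all five labels and is extension-invariant", {
  net1 <- parse_rules("A* = A")
  expect_equal(classify_node_pattern(find_attractor(net1, c(A = 1L)), "A"),
               "CONSTANT_ON")
  expect_equal(classify_node_pattern(find_attractor(net1, c(A = 0L)), "A"),
               "CONSTANT_OFF")
  expect_equal(classify_node_pattern(find_attractor(negative_feedback_net()),
                                     "DUSP"), "OSCILLATING")
  drain <- parse_rules(c("#input: In", "A* = In",
                         "In = False", "A = True"))
  expect_equal(classify_node_pattern(find_attractor(drain), "A"),
               "ON_THEN_OFF")
  fill <- parse_rules(c("#input: In", "A* = In",
                        "In = True", "A = False"))
  expect_equal(classify_node_pattern(find_attractor(fill), "A"),
               "OFF_THEN_ON")
  expect_error(classify_node_pattern(find_attractor(net1, c(A = 1L)), "Z"),
               "unknown node")
  # classification reads the attractor, so it cannot depend on how long a
  # trajectory one simulates beyond the cycle
  att <- find_attractor(negative_feedback_net())
  expect_equal(classify_node_pattern(att, "ERK"), "OSCILLATING")
})

test_that("trajectory export writes a faithful TSV that round-trips", {
  net <- negative_feedback_net()
  tr <- simulate_network(net, n_steps = 3)
  prefix <- file.path(withr::local_tempdir(), "traj")
  export_heatmap(tr, prefix)
  m <- read_trajectory_tsv(paste0(prefix, ".tsv"))
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(unname(m), unname(unclass(tr)[, ]))
  expect_equal(rownames(m), net$nodes)
  # all-OFF trajectory gives an all-zero matrix
  off <- parse_rules(c("A* = A", "B* = A", "A = False", "B = False"))
  tr0 <- simulate_network(off, n_steps = 2)
  prefix0 <- file.path(withr::local_tempdir(), "traj0")
  export_heatmap(tr0, prefix0)
  expect_true(all(read_trajectory_tsv(paste0(prefix0, ".tsv")) == 0))
})

test_that("node_symbols encodes transitions over transient plus one cycle", {
  att <- find_attractor(negative_feedback_net())
  s <- node_symbols(att, "ERK")
  expect_match(s, "^[-+0]+$")
  expect_true(grepl("\\+", s) && grepl("-", s))
  idn <- find_attractor(parse_rules("A* = A"), c(A = 1L))
  expect_equal(node_symbols(idn, "A"), "0")
})
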