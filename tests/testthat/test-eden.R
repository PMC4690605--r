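# Stochastic Eden engine: exact bookkeeping invariants, event statistics,
# and genealogy correctness against an event-log replay oracle.

test_that("initialization: unique genotypes, disk raster, reproducibility", {
  cfg <- eden_config(W = 600L, R = 80L, config = "single")
  st <- frontobstacles:::eden_build_state(cfg)
  genos <- st[st > 0L]
  expect_equal(sort(unique(genos)), 1:600)          # all-unique founding row
  # disk raster site count close to pi R^2 (unit cell area = sqrt(3)/2)
  n_blocked <- sum(st == -1L) - 2L * cfg$n_rows     # walls excluded
  expect_lt(abs(n_blocked - pi * 80^2 / (sqrt(3) / 2)) / (pi * 80^2 / (sqrt(3) / 2)),
            0.02)

  cfg2 <- eden_config(W = 40L, R = 6L, config = "single")
  s1 <- eden_run(cfg2, seed = 11)
  s2 <- eden_run(cfg2, seed = 11)
  expect_identical(s1$state, s2$state)
  expect_identical(s1$ev_time, s2$ev_time)

  expect_error(eden_config(W = 40L, R = 6L, centers = matrix(c(20, 3), 1)),
               class = "invalid_geometry")          # overlaps the founding row
})

test_that("a lone founder with two empty neighbors fills each first with probability 1/2", {
  # custom lattice: 1 occupied site whose only empty neighbors are the two
  # sites above it
  nrow <- 3L; ncol <- 5L
  init <- rep(0L, nrow * ncol)
  init[c(1, 5, 6, 10, 11, 15)] <- -1L               # side walls
  init[2] <- -1L; init[4] <- -1L                    # block flanking row-0 sites
  init[3] <- 7L                                     # single founder, genotype 7
  counts <- c(0L, 0L)
  for (s in 1:400) {
    set.seed(s)
    res <- frontobstacles:::eden_run_cpp(init, nrow, ncol, 2L, 1L)
    child <- res$ev_child[1]
    expect_true(child %in% c(7L, 8L))                # the two row-1 neighbors
    counts[child - 6L] <- counts[child - 6L] + 1L
  }
  # binomial(400, 1/2): three sigma is 30
  expect_lt(abs(counts[1] - 200), 30)
})

test_that("event clock and conservation: one site per event, Exp(1/|F|) increments", {
  cfg <- eden_config(W = 80L, R = 10L, config = "single")
  sim <- eden_run(cfg, seed = 5)
  expect_equal(sim$n_events, sum(sim$state > 0L) - cfg$W)
  expect_true(all(diff(sim$ev_time) > 0))
  # dt * |F| ~ Exp(1): empirical mean within 3 standard errors of 1
  dt <- diff(c(0, sim$ev_time))
  z <- dt * sim$ev_frontier_size
  expect_lt(abs(mean(z) - 1), 3 / sqrt(length(z)))
  # no occupied site inside the obstacle, ever (blocked never changes)
  expect_equal(sum(sim$state == -1L),
               sum(frontobstacles:::eden_build_state(cfg) == -1L))
})

test_that("genealogy matches a from-scratch replay of the event log (small lattices)", {
  cfg <- eden_config(W = 18L, config = "none", stop_depth = 8, extra_rows = 9L)
  expect_lte(cfg$n_rows, 20L); expect_lte(cfg$n_cols, 20L)
  for (s in 1:3) {
    sim <- eden_run(cfg, seed = s)
    rep <- eden_replay(sim)[[1]]
    expect_identical(rep$state, sim$state)
    expect_identical(rep$parent, sim$parent)
    expect_setequal(rep$frontier, sim$frontier)
    # ancestry of every frontier site agrees with walking the replayed parents
    fo <- genealogy(sim)
    for (k in seq_along(fo$tips)) {
      path <- fo$paths[[k]]
      s2 <- fo$tips[k]; oracle <- s2
      while (rep$parent[s2] > 0L) { s2 <- rep$parent[s2]; oracle <- c(s2, oracle) }
      expect_identical(path, oracle)
    }
  }
})

test_that("lineage forests are rooted in the founding row with decreasing birth times", {
  cfg <- eden_config(W = 60L, R = 8L, config = "single")
  sim <- eden_run(cfg, seed = 2)
  fo <- genealogy(sim)
  rc <- frontobstacles:::site_rc(fo$roots, cfg$n_cols)
  expect_true(all(rc[, 1] == 0L))
  bt <- sim$btime
  expect_true(all(bt[fo$edges$child] > bt[fo$edges$parent]))
  # immediately after init the forest is the frontier itself
  sim0 <- eden_run(cfg, seed = 2, max_events = 0L)
  fo0 <- genealogy(sim0)
  expect_equal(nrow(fo0$edges), 0L)
  expect_setequal(fo0$tips, sim0$frontier)
})

test_that("sector boundaries: founding row count, monoclonal emptiness, coarsening", {
  cfg <- eden_config(W = 60L, config = "none", stop_depth = 40)
  sim <- eden_run(cfg, seed = 9)
  sb0 <- sector_boundaries(sim, rows = c(0L, 0L))
  expect_equal(nrow(sb0), cfg$W - 1L)               # all founders distinct
  # a monoclonal patch has no boundaries: repaint and check
  simu <- sim; simu$state[simu$state > 0L] <- 1L
  expect_equal(nrow(sector_boundaries(simu)), 0L)
  # frontier genotype count is non-increasing (lost genotypes never return)
  snaps <- eden_replay(sim, at_events = round(seq(100, sim$n_events, length.out = 8)))
  counts <- vapply(snaps, function(s) length(s$frontier_genotypes), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("pinned-boundary detection handles the no-obstacle and not-ready contracts", {
  cfg <- eden_config(W = 60L, config = "none", stop_depth = 30)
  sim <- eden_run(cfg, seed = 1)
  expect_error(detect_pinned_boundary(sim), class = "not_applicable")
  cfg2 <- eden_config(W = 60L, R = 8L, config = "single")
  sim2 <- eden_run(cfg2, seed = 1, max_events = 500L)
  expect_error(detect_pinned_boundary(sim2), class = "not_ready")
  expect_equal(nrow(classify_lineage_route(sim)), 0L)
})

test_that("lineage routes around a symmetric obstacle use both sides across seeds", {
  cfg <- eden_config(W = 80L, R = 10L, config = "single")
  sides <- character(0)
  for (s in 1:6) {
    sim <- eden_run(cfg, seed = s)
    cr <- classify_lineage_route(sim)
    sides <- c(sides, unique(cr$side))
  }
  expect_setequal(unique(sides), c("left", "right"))
})

test_that("newick export encodes every tip and parses", {
  cfg <- eden_config(W = 12L, config = "none", stop_depth = 6, extra_rows = 14L)
  sim <- eden_run(cfg, seed = 4)
  fo <- genealogy(sim)
  nwk <- lineage_newick(fo)
  expect_equal(length(nwk), length(fo$roots))
  expect_true(all(grepl(";$", nwk)))
  skip_if_not_installed("ape")
  trees <- lapply(nwk, function(s) ape::read.tree(text = s))
  expect_true(all(!vapply(trees, is.null, TRUE)))
  labs <- unlist(lapply(trees, function(t) c(t$tip.label, t$node.label)))
  expect_true(all(sprintf("s%d", fo$tips) %in% labs))
})
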