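test_that("null dynamics change nothing but the clock", {
  set.seed(30)
  p <- null_params(n_init = 25)
  st <- init_cell_state(p)
  st2 <- step(st, p)
  expect_equal(st2$time, st$time + p$dt)
  expect_identical(st2$pos, st$pos)
  expect_identical(st2$hu, st$hu)
  expect_identical(st2$bonds, st$bonds)
  expect_equal(nrow(attr(st2, "events")), 0)
})

test_that("identical seeds and parameters give bit-identical trajectories", {
  p <- make_fixture("tiny-default")
  a <- run(p, seed = 31)
  b <- run(p, seed = 31)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$final_state$pos, b$final_state$pos)
})

test_that("R-level sub-step composition equals the compiled run loop", {
  p <- make_fixture("tiny-default")
  n_steps <- 40

  set.seed(32)
  st <- init_cell_state(p)
  for (i in seq_len(n_steps)) {
    st <- damage_step(st, p)
    st <- transport_step(st, p)
    cg <- contacts(st, p)
    st <- fusion_step(st, cg, p)
    st <- fission_step(st, p)
    st <- autophagy_step(st, p)
    st <- replicate_step(st, p)
    st$time <- st$time + p$dt
  }

  p2 <- validate_params(utils::modifyList(
    unclass(p), list(t_sim = n_steps, record_interval = n_steps)))
  tr <- run(p2, seed = 32)
  fin <- tr$final_state

  expect_equal(fin$time, st$time)
  expect_identical(fin$id, st$id)
  expect_equal(fin$pos, st$pos, tolerance = 1e-14)
  expect_identical(fin$hu, st$hu)
  expect_identical(fin$motion, st$motion)
  expect_identical(fin$bonds, st$bonds)
  expect_identical(fin$cum_autophagy, st$cum_autophagy)
  expect_identical(fin$cum_replication, st$cum_replication)
})

test_that("population bookkeeping closes at every sample", {
  p <- make_fixture("tiny-default")
  tr <- run(p, seed = 33)
  s <- tr$samples
  expect_equal(s$n_mito,
               p$n_init + s$cum_replication - s$cum_autophagy)
  # and the cumulative counters agree with the event log
  expect_equal(max(s$cum_autophagy), sum(tr$events$kind == "autophagy"))
  expect_equal(max(s$cum_replication), sum(tr$events$kind == "replication"))
})

test_that("a zero-length simulation records only the initial state", {
  p <- validate_params(utils::modifyList(
    unclass(make_fixture("tiny-default")), list(t_sim = 0)))
  tr <- run(p, seed = 34)
  expect_equal(nrow(tr$samples), 1)
  expect_equal(tr$samples$time, 0)
  expect_equal(tr$samples$n_mito, p$n_init)
})

test_that("initial health is Binomial(n_HU, 1/2)-distributed with mean 0.5", {
  p <- make_fixture("tiny-default")
  ens <- run_ensemble(p, n_cells = 6, master_seed = 35)
  h0 <- unlist(lapply(ens, function(tr) tr$healths[[1]]))
  n_units <- length(h0) * p$n_HU
  se <- sqrt(0.25 / n_units)
  expect_lt(abs(mean(h0) - 0.5), 3 * se)
})

test_that("ensembles reproduce and reduce to single runs", {
  p <- make_fixture("tiny-default")
  e1 <- run_ensemble(p, n_cells = 1, master_seed = 36)
  single <- run(p, seed = attr(e1, "cell_seeds")[1])
  expect_identical(e1[[1]]$samples, single$samples)

  e2 <- run_ensemble(p, n_cells = 3, master_seed = 36)
  e3 <- run_ensemble(p, n_cells = 3, master_seed = 36)
  for (i in 1:3) expect_identical(e2[[i]]$samples, e3[[i]]$samples)
  expect_equal(length(e2), 3)
})

test_that("no mitochondrion fuses and is removed in the same step", {
  # overlap zone h_fus < health < h_aut makes both events possible in
  # principle; sub-step ordering must still forbid the coincidence
  p <- mito_params(n_init = 40, N0 = 40, sigma_N = 4, t_sim = 1500,
                   L = side_for_filling(40, 0.5, 0.19),
                   h_fus = 0.1, h_aut = 0.5)
  tr <- run(p, seed = 37)
  ev <- tr$events
  aut <- ev[ev$kind == "autophagy", c("time", "id1")]
  fus <- ev[ev$kind == "fusion", c("time", "id1", "id2")]
  expect_gt(nrow(aut), 0)
  expect_gt(nrow(fus), 0)
  clash <- merge(aut, data.frame(time = fus$time,
                                 id1 = c(fus$id1, fus$id2)))
  expect_equal(nrow(clash), 0)
})
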