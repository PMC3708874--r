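test_that("zero damage rate leaves every health unit untouched", {
  set.seed(10)
  p <- null_params()
  st <- init_cell_state(mito_params(n_init = 30))
  st2 <- damage_step(st, p)
  expect_identical(st2$hu, st$hu)
})

test_that("damage-only decay follows the unit-survival closed form", {
  # each healthy unit survives to time t with probability exp(-k_d t), so
  # the ensemble mean health is 0.5 * exp(-k_d t) from a Bernoulli(1/2) start
  p <- make_fixture("damage-only")
  p <- validate_params(utils::modifyList(unclass(p), list(t_sim = 2000)))
  ens <- run_ensemble(p, n_cells = 4, master_seed = 11)
  finals <- unlist(lapply(ens, function(tr) tr$healths[[length(tr$healths)]]))
  n_units <- length(finals) * p$n_HU
  p_unit <- 0.5 * exp(-p$k_damage * p$t_sim)
  se <- sqrt(p_unit * (1 - p_unit) / n_units)
  expect_lt(abs(mean(finals) - p_unit), 3 * se)
  # population exactly constant without autophagy or replication
  for (tr in ens) expect_true(all(tr$samples$n_mito == p$n_init))
})

test_that("exchange conserves healthy units and hits forced outcomes", {
  set.seed(12)
  for (i in 1:25) {
    n_HU <- sample(2:12, 1)
    a <- sample(c(0L, 1L), n_HU, replace = TRUE)
    b <- sample(c(0L, 1L), n_HU, replace = TRUE)
    n_ex <- sample(0:n_HU, 1)
    out <- exchange_units(a, b, n_ex)
    expect_equal(sum(out$a) + sum(out$b), sum(a) + sum(b))
    expect_equal(length(out$a), n_HU)
  }
  # all-healthy vs all-damaged with n = 2: healths 0.8 / 0.2 in every draw
  for (i in 1:10) {
    out <- exchange_units(rep(1L, 10), rep(0L, 10), 2)
    expect_equal(sum(out$a), 8L)
    expect_equal(sum(out$b), 2L)
  }
  out0 <- exchange_units(hu_frac(3), hu_frac(9), 0)
  expect_identical(out0$a, hu_frac(3))
  expect_identical(out0$b, hu_frac(9))
  expect_error(exchange_units(rep(1L, 10), rep(0L, 10), 11), "n must")
})

test_that("asymmetry generation peaks at half the units exchanged", {
  # exhaustive enumeration over all position choices for two equal-health
  # parents (5 of 10 healthy): P(healths differ after exchange)
  a <- hu_frac(5)
  p_asym <- vapply(0:10, function(n_ex) {
    pmf <- exchange_pmf(a, a, n_ex)
    1 - sum(pmf[names(pmf) == "5"])
  }, numeric(1))
  expect_equal(which.max(p_asym) - 1L, 5L)
  # exchanging n and N - n units is equivalent up to relabeling
  for (n_ex in 0:5) {
    expect_equal(p_asym[n_ex + 1], p_asym[11 - n_ex], tolerance = 1e-12)
  }
  # cross-check: independent hypergeometric collision probability
  p_hyper <- vapply(0:10, function(n_ex) {
    1 - sum(stats::dhyper(0:n_ex, 5, 5, n_ex)^2)
  }, numeric(1))
  expect_equal(p_asym, p_hyper, tolerance = 1e-12)
})

test_that("simulated exchange matches the enumerated distribution", {
  # n_HU = 6 exhaustive case: empirical distribution of post-exchange
  # healthy counts in `a` against the enumeration oracle
  a <- c(1L, 1L, 1L, 0L, 0L, 0L)
  b <- c(1L, 0L, 1L, 0L, 1L, 0L)
  pmf <- exchange_pmf(a, b, 2)
  set.seed(13)
  draws <- replicate(3000, sum(exchange_units(a, b, 2)$a))
  obs <- table(factor(draws, levels = names(pmf)))
  chi <- stats::chisq.test(obs, p = pmf)
  expect_gt(chi$p.value, 1e-3)
})

test_that("fission breaks bonds at the stated rate and conserves units", {
  p <- null_params(k_fis = 0.1, n_exchange = 2)
  st0 <- make_state(rbind(c(5, 5), c(6, 5)),
                    hu = rbind(hu_frac(9), hu_frac(3)),
                    bonds = rbind(c(1L, 2L)))
  # k_fis = 0: the bond never breaks
  p0 <- null_params()
  st <- st0
  set.seed(14)
  for (i in 1:50) st <- fission_step(st, p0)
  expect_equal(nrow(st$bonds), 1)

  # lifetime is geometric with per-step probability 1 - exp(-k_fis dt)
  set.seed(15)
  lives <- replicate(400, {
    st <- st0
    steps <- 0
    while (nrow(st$bonds) > 0) {
      st <- fission_step(st, p)
      steps <- steps + 1
    }
    steps
  })
  expected_mean <- 1 / (1 - exp(-p$k_fis * p$dt))
  se <- stats::sd(lives) / sqrt(length(lives))
  expect_lt(abs(mean(lives) - expected_mean), 3 * se)

  # healthy units conserved across every logged fission
  set.seed(16)
  pfull <- mito_params(t_sim = 400, n_init = 40, N0 = 40, sigma_N = 4,
                       L = side_for_filling(40, 0.5, 0.19))
  tr <- run(pfull, seed = 1)
  fis <- tr$events[tr$events$kind == "fission", ]
  expect_gt(nrow(fis), 10)
  expect_equal(fis$h_a + fis$h_b, fis$h_a_post + fis$h_b_post,
               tolerance = 1e-9)
})

test_that("autophagy is selective, size-limited, and strictly sub-threshold", {
  p <- null_params(k_aut = 5) # near-certain removal per step when eligible
  # fused mitochondria are never removed, whatever their health
  st <- make_state(rbind(c(5, 5), c(6, 5)),
                   hu = rbind(hu_frac(0), hu_frac(0)),
                   bonds = rbind(c(1L, 2L)))
  set.seed(17)
  for (i in 1:20) st <- autophagy_step(st, p)
  expect_equal(nrow(st$pos), 2)

  # at the threshold (health 0.3 = h_aut) a mitochondrion is kept;
  # strictly below it is removed
  st <- make_state(rbind(c(5, 5), c(10, 10)),
                   hu = rbind(hu_frac(3), hu_frac(2)))
  st <- autophagy_step(st, p)
  expect_equal(nrow(st$pos), 1)
  expect_equal(mito_health(st$hu[1, ]), 0.3)

  # waiting time at the default rate: survival over t steps is exp(-k_aut t),
  # giving a mean waiting time of ~300 min
  p2 <- null_params(k_aut = 3.33e-3, L = 500)
  n <- 300
  set.seed(18)
  st <- make_state(cbind(runif(n, 30, 470), runif(n, 30, 470)),
                   hu = matrix(rep(hu_frac(2), n), n, 10, byrow = TRUE))
  t_end <- 300
  for (i in seq_len(t_end)) st <- autophagy_step(st, p2)
  expected <- n * exp(-p2$k_aut * t_end)
  se <- sqrt(expected * (1 - expected / n))
  expect_lt(abs(nrow(st$pos) - expected), 3 * se + 1)
})

test_that("replication rate is population-limited with the stated shape", {
  p <- mito_params()
  expect_equal(replication_rate(p$N0, p), p$k_rep / 2)
  ns <- seq(0, 600, by = 10)
  rates <- replication_rate(ns, p)
  expect_true(all(diff(rates) <= 1e-12))
  expect_lt(rates[length(rates)], 1e-8)
  # far above N0 the per-step event probability is negligible
  n_hi <- p$N0 + 10 * p$sigma_N
  prob <- 1 - exp(-n_hi * replication_rate(n_hi, p) * p$dt)
  expect_lt(prob, 1e-3)
})

test_that("replication copies the progenitor and respects caps", {
  # cap 0: population can never grow
  p <- null_params(k_rep = 100, N0 = 1e6, sigma_N = 10, cap_replication = 0)
  st <- make_state(rbind(c(5, 5), c(10, 10)))
  set.seed(19)
  for (i in 1:30) st <- replicate_step(st, p)
  expect_equal(nrow(st$pos), 2)

  # daughters inherit the health-unit vector exactly
  p2 <- null_params(k_rep = 100, N0 = 1e6, sigma_N = 10)
  hu <- rbind(hu_frac(7), hu_frac(7))
  st <- make_state(rbind(c(5, 5), c(10, 10)), hu = hu)
  st2 <- replicate_step(st, p2)
  expect_equal(nrow(st2$pos), 3)
  expect_equal(mito_health(st2$hu[3, ]), 0.7)
  expect_equal(st2$motion[3], 0L)
  ev <- attr(st2, "events")
  expect_equal(ev$kind, "replication")
})

test_that("the trailing window cap counts only recent events", {
  expect_true(window_allows(numeric(0), Inf, 1000))
  expect_true(window_allows(seq(0, 5000, by = 10), Inf, 5000))
  expect_false(window_allows(c(10, 40, 80, 120, 150, 170), 5, 180))
  # two of six events older than 180 minutes: allowed again
  expect_true(window_allows(c(10, 40, 230, 260, 300, 350), 5, 400))
  expect_false(window_allows(c(100), 0, 100))
})

test_that("windowed caps bound events in every trailing window of a run", {
  p <- mito_params(n_init = 30, N0 = 30, sigma_N = 3, t_sim = 1500,
                   L = side_for_filling(30, 0.5, 0.19),
                   cap_autophagy = 3, cap_replication = 4)
  tr <- run(p, seed = 20)
  for (kind in c("autophagy", "replication")) {
    cap <- if (kind == "autophagy") 3 else 4
    times <- tr$events$time[tr$events$kind == kind]
    if (length(times) > 0) {
      # at each event, the count of earlier events in its trailing window
      # must have been below the cap
      for (k in seq_along(times)) {
        n_before <- sum(times > times[k] - 180 & times < times[k])
        expect_lt(n_before, cap)
      }
    }
  }
})
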