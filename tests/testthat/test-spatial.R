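test_that("filling fraction follows the disk-area formula", {
  expect_equal(filling_fraction(0, 0.5, 25), 0)
  expect_equal(filling_fraction(150, 0.5, 25), 150 * pi * 0.25 / 625)
  phi <- 0.55
  L <- side_for_filling(150, 0.5, phi)
  expect_equal(filling_fraction(150, 0.5, L), phi)
})

test_that("placement is uniform within walls and free of overlap", {
  set.seed(1)
  one <- place_non_overlapping(1, 25, 0.5)
  expect_true(all(one >= 0.5 & one <= 24.5))

  pos <- place_non_overlapping(150, 25, 0.5)
  expect_equal(dim(pos), c(150, 2))
  expect_gte(min(dist(pos)), 1.0)
  expect_true(all(pos >= 0.5 & pos <= 24.5))

  expect_error(place_non_overlapping(2000, 25, 0.5), "infeasible packing")
})

test_that("dense lattice placement reaches 55% filling without overlap", {
  set.seed(2)
  L <- side_for_filling(150, 0.5, 0.55)
  pos <- mitonet:::place_lattice_jitter(150, L, 0.5)
  expect_equal(nrow(pos), 150)
  expect_gte(min(dist(pos)), 1.0 - 1e-9)
  expect_true(all(pos >= 0.5 - 1e-12 & pos <= L - 0.5 + 1e-12))
})

test_that("transport leaves stationary mitochondria alone when k_on = 0", {
  set.seed(3)
  p <- null_params()
  st <- init_cell_state(p)
  st2 <- transport_step(st, p)
  expect_identical(st2$pos, st$pos)
  expect_identical(st2$motion, st$motion)
})

test_that("a free mover advances exactly v*dt and stops at obstacles", {
  p <- null_params()

  # free path: one mover aimed along +x in an empty cell
  st <- make_state(c(5, 5), motion = 1L, theta = 0)
  st2 <- transport_step(st, p)
  expect_equal(st2$pos[1, ], c(x = 5.5, y = 5), tolerance = 1e-12)
  expect_equal(st2$motion[1], 1L) # unobstructed, k_off = 0: stays bound

  # contact stop: an obstacle 1.2 um ahead; mover halts at center
  # distance 2r = 1.0 and detaches
  st <- make_state(rbind(c(5, 5), c(6.2, 5)), motion = c(1L, 0L),
                   theta = c(0, 0))
  st2 <- transport_step(st, p)
  expect_equal(unname(st2$pos[1, 1]), 5.2, tolerance = 1e-9)
  expect_equal(st2$motion[1], 0L)

  # wall stop: mover 0.2 um from the wall halts at x = L - r, detaches
  st <- make_state(c(24.3, 5), motion = 1L, theta = 0)
  st2 <- transport_step(st, p)
  expect_equal(unname(st2$pos[1, 1]), 24.5, tolerance = 1e-12)
  expect_equal(st2$motion[1], 0L)
})

test_that("no step creates overlap or pushes centers outside the walls", {
  set.seed(4)
  p <- mito_params(n_init = 60, L = 10, k_on = 2, k_off = 0.1,
                   k_fus = 0, k_fis = 0, k_aut = 0, k_rep = 0, k_damage = 0)
  st <- init_cell_state(p)
  for (i in 1:80) {
    st <- transport_step(st, p)
    expect_gte(min(dist(st$pos)), 2 * p$r - 1e-9)
    expect_true(all(st$pos >= p$r - 1e-12 & st$pos <= p$L - p$r + 1e-12))
  }
})

test_that("contact detection equals the brute-force pair scan", {
  p <- mito_params(tol = 0.01)

  # threshold cases: touching at exactly 2r, separated at 1.5 um
  st <- make_state(rbind(c(5, 5), c(6, 5), c(6, 6.5)))
  cg <- contacts(st, p)
  expect_equal(nrow(cg), 1)
  expect_equal(c(cg$id1, cg$id2), c(1L, 2L))

  set.seed(5)
  for (rep in 1:5) {
    pos <- place_non_overlapping(150, 18, 0.5)
    st <- make_state(pos)
    cg <- contacts(st, p)
    bf <- brute_contacts(st, p$r, p$tol)
    got <- if (nrow(cg)) cg[order(cg$id1, cg$id2), c("id1", "id2")] else NULL
    if (is.null(bf)) {
      expect_equal(nrow(cg), 0)
    } else {
      bf <- bf[order(bf[, 1], bf[, 2]), , drop = FALSE]
      expect_equal(unname(as.matrix(got)), unname(bf))
    }
  }
})

test_that("contact pairs carry the motility class of the last transport", {
  # binds almost surely each step; negligible speed keeps the pair touching
  p <- null_params(k_on = 50, v = 1e-9)
  set.seed(6)
  st <- make_state(rbind(c(5, 5), c(6.005, 5)), bonds = NULL)
  st <- transport_step(st, p)
  cg <- contacts(st, p)
  expect_equal(nrow(cg), 1)
  expect_equal(as.character(cg$class), "both_moving")

  # fused mitochondria never move, so a bonded pair is neither-moving
  stb <- make_state(rbind(c(5, 5), c(6.005, 5)), bonds = rbind(c(1L, 2L)))
  stb <- transport_step(stb, p)
  cgb <- contacts(stb, p)
  expect_equal(as.character(cgb$class), "neither_moving")
})

test_that("isolated-mitochondrion dispersal matches persistent diffusion", {
  # effective diffusivity of the run-and-pause walk: D = v^2 p_m / (2 k_off)
  # with p_m = k_on / (k_on + k_off); MSD(t) = 4 D t at long times
  set.seed(7)
  k_on <- 0.1
  k_off <- 0.05
  v <- 0.5
  p <- null_params(k_on = k_on, k_off = k_off, v = v, L = 5e4, n_init = 0)
  n <- 80
  # start well separated so contact truncation never triggers
  gx <- rep(seq_len(10), length.out = n) * 4000
  gy <- rep(seq_len(8), each = 10)[seq_len(n)] * 4000
  st <- make_state(cbind(gx, gy))
  start <- st$pos
  n_steps <- 4000
  for (i in seq_len(n_steps)) st <- transport_step(st, p)
  disp2 <- rowSums((st$pos - start)^2)
  msd <- mean(disp2)
  d_eff <- v^2 * (k_on / (k_on + k_off)) / (2 * k_off)
  expected <- 4 * d_eff * n_steps
  # r^2 is approximately exponential => sd(disp2) ~ mean(disp2)
  se <- stats::sd(disp2) / sqrt(n)
  expect_lt(abs(msd - expected), 3 * se)
})
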