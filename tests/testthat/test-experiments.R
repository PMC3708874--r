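test_that("fixtures preserve the model's dimensionless ratios", {
  tiny <- make_fixture("tiny-default")
  phi_default <- filling_fraction(150, 0.5, 25)
  expect_lt(abs(filling_fraction(tiny$n_init, tiny$r, tiny$L) /
                  phi_default - 1), 0.01)
  expect_equal(tiny$N0, tiny$n_init)

  dmg <- make_fixture("damage-only")
  expect_true(all(c(dmg$k_fus, dmg$k_fis, dmg$k_aut, dmg$k_rep,
                    dmg$k_on) == 0))
  expect_gt(dmg$k_damage, 0)

  crw <- make_fixture("crowded")
  expect_lt(abs(filling_fraction(crw$n_init, crw$r, crw$L) - 0.55), 0.006)

  expect_error(make_fixture("nope"), "unknown fixture")
})

test_that("experiment specs validate their scan axes", {
  base <- make_fixture("tiny-default")
  expect_error(experiment_spec("x", base, axes = list(bogus = 1:3)),
               "unknown scan axis")
  expect_error(
    experiment_spec("x", base,
                    axes = list(arm = list(a = list(bogus = 1)))),
    "unknown field")
  sp <- experiment_spec("x", base, axes = list(n_exchange = c(0, 5)),
                        n_cells = 2)
  expect_s3_class(sp, "experiment_spec")
})

test_that("experiments expand grids and reproduce bit-exactly", {
  base <- validate_params(utils::modifyList(
    unclass(make_fixture("tiny-default")), list(t_sim = 300)))
  sp <- experiment_spec(
    "grid", base,
    axes = list(n_exchange = c(2, 5), k_fus = c(0.05, 0.1)),
    n_cells = 2, window = c(150, 300))
  r1 <- run_experiment(sp, master_seed = 50)
  expect_equal(nrow(r1$points), 4)
  expect_equal(nrow(r1$cells), 8)
  expect_setequal(names(r1$points)[1:2], c("n_exchange", "k_fus"))

  r2 <- run_experiment(sp, master_seed = 50)
  expect_identical(r1$points, r2$points)
  expect_identical(r1$cells, r2$cells)
})

test_that("the filling-fraction axis adjusts the cell side", {
  base <- validate_params(utils::modifyList(
    unclass(make_fixture("tiny-default")), list(t_sim = 100)))
  sp <- experiment_spec("density", base,
                        axes = list(filling_fraction = c(0.05, 0.19)),
                        n_cells = 1, window = c(50, 100))
  res <- run_experiment(sp, master_seed = 51)
  expect_equal(res$points$filling_fraction, c(0.05, 0.19))
  # denser cells see more fusion
  expect_gt(res$points$fusion_per_hr[2], res$points$fusion_per_hr[1])
})

test_that("presets define the documented scans", {
  sp4 <- experiment_preset("exchange-scan", n_cells = 2, t_sim = 100)
  expect_equal(sp4$axes$n_exchange, 0:10)
  sp5 <- experiment_preset("threshold-grid")
  expect_equal(length(sp5$axes$h_aut) * length(sp5$axes$h_fus), 49)
  sp6 <- experiment_preset("density-scan")
  expect_true(0.55 %in% sp6$axes$filling_fraction)
  sp7 <- experiment_preset("motility-scan")
  combos <- sp7$axes$motility
  expect_true(all(vapply(combos, function(x) x$beta <= x$alpha,
                         logical(1))))
  sp9 <- experiment_preset("discreteness-scan")
  expect_true(all(vapply(sp9$axes$discreteness,
                         function(x) x$n_exchange == x$n_HU / 5,
                         logical(1))))
  sp3 <- experiment_preset("nested-models")
  expect_equal(names(sp3$axes$model)[1], "damage")
  expect_error(experiment_preset("fig42"), "unknown experiment preset")
})

test_that("transport calibration reports its grid and best point", {
  p <- validate_params(utils::modifyList(
    unclass(make_fixture("tiny-default")), list(t_sim = 200)))
  res <- suppressWarnings(calibrate_transport(
    targets = list(fractions = c(0.6, 0.35, 0.05), events_per_hr = 40),
    p = p, k_on_grid = c(1, 8), k_off_grid = 0.01,
    n_cells = 2, t_sim = 200, window = c(100, 200), master_seed = 52))
  expect_equal(nrow(res$grid), 2)
  expect_true(res$k_on %in% c(1, 8))
  expect_true(is.finite(res$objective))
  expect_true(all(c("frac_both", "events_per_hr") %in% names(res$grid)))
})
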