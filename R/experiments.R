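#' Define a parameter-scan experiment
#'
#' An experiment is a Cartesian product of scan axes over a base parameter
#' set, run as an independent ensemble per grid point and summarized over a
#' steady-state window.
#'
#' Each element of `axes` is either
#' * a numeric vector named after a parameter field (e.g.
#'   `n_exchange = 0:10`), or the special field `filling_fraction`, which is
#'   realized by adjusting the cell side at fixed population, or
#' * a named list of parameter patches (each a named list of field values),
#'   for scan arms that move several fields together (e.g. `n_HU` with a
#'   proportional `n_exchange`).
#'
#' @param name experiment name.
#' @param base a `mito_params` object (the scan modifies copies of it).
#' @param axes named list of scan axes (see Details).
#' @param n_cells ensemble size per grid point.
#' @param window steady-state window `c(start, end)` in minutes, or `NULL`
#'   for the final 2000 minutes.
#' @return An object of class `experiment_spec`.
#' @seealso [run_experiment()], [experiment_preset()]
#' @export
experiment_spec <- function(name, base = mito_params(), axes = list(),
                            n_cells = base$n_cells, window = NULL) {
  base <- validate_params(unclass(base))
  stopifnot(is.list(axes), n_cells >= 1)
  if (length(axes) > 0 && is.null(names(axes))) {
    stop("axes must be a named list")
  }
  valid <- c(names(formals(mito_params)), "filling_fraction")
  for (ax in names(axes)) {
    vals <- axes[[ax]]
    if (is.numeric(vals)) {
      if (!(ax %in% valid)) stop("unknown scan axis field: ", ax)
    } else if (is.list(vals)) {
      for (patch in vals) {
        bad <- setdiff(names(patch), valid)
        if (length(bad) > 0) {
          stop("patch in axis '", ax, "' references unknown field(s): ",
               paste(bad, collapse = ", "))
        }
      }
    } else {
      stop("axis '", ax, "' must be a numeric vector or a list of patches")
    }
  }
  structure(list(name = name, base = base, axes = axes,
                 n_cells = as.integer(n_cells), window = window),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  np <- prod(vapply(x$axes, length, integer(1)))
  if (length(x$axes) == 0) np <- 1
  cat(sprintf("experiment '%s': %d grid point(s) x %d cells\n",
              x$name, np, x$n_cells))
  for (ax in names(x$axes)) {
    v <- x$axes[[ax]]
    lab <- if (is.numeric(v)) paste(format(v), collapse = ", ") else
      paste(names(v), collapse = ", ")
    cat(sprintf("  %s: %s\n", ax, lab))
  }
  invisible(x)
}

apply_axis_value <- function(p, axis, value) {
  p <- unclass(p)
  if (is.list(value)) { # patch
    for (f in names(value)) p <- apply_axis_value(p, f, value[[f]])
    return(p)
  }
  if (axis == "filling_fraction") {
    p$L <- side_for_filling(p$n_init, p$r, value)
  } else {
    p[[axis]] <- value
  }
  p
}

#' Run a parameter-scan experiment
#'
#' Expands the Cartesian product of the scan axes, runs an independent
#' ensemble at every grid point (per-point master seeds derived
#' deterministically from `master_seed`), and summarizes each point over
#' the steady-state window.
#'
#' @param spec an `experiment_spec`.
#' @param master_seed master RNG seed.
#' @return An object of class `experiment_result`: list with
#'   \describe{
#'     \item{points}{data frame, one row per grid point: axis values plus
#'       `mean_health`, `p25_health`, `p75_health`, `mean_population`,
#'       `fusion_per_hr`, `frac_both`, `frac_one`, `frac_neither`,
#'       `n_empty_samples`.}
#'     \item{cells}{data frame, one row per (point, cell) with the same
#'       summary columns per cell.}
#'     \item{spec, master_seed}{inputs, for provenance.}
#'   }
#' @examples
#' sp <- experiment_spec("exchange", make_fixture("tiny-default"),
#'                       axes = list(n_exchange = c(0, 5)), n_cells = 2)
#' res <- run_experiment(sp, master_seed = 1)
#' res$points
#' @export
run_experiment <- function(spec, master_seed = 1) {
  stopifnot(inherits(spec, "experiment_spec"))
  axes <- spec$axes
  lens <- if (length(axes) > 0) vapply(axes, length, integer(1)) else
    integer(0)
  grid <- if (length(axes) > 0) {
    do.call(expand.grid, c(lapply(lens, seq_len), KEEP.OUT.ATTRS = FALSE))
  } else {
    data.frame(.point = 1)
  }
  n_points <- nrow(grid)
  seeds <- derive_seeds(master_seed, n_points)

  point_rows <- vector("list", n_points)
  cell_rows <- vector("list", n_points)
  for (pt in seq_len(n_points)) {
    p <- unclass(spec$base)
    labels <- list()
    for (ax in names(axes)) {
      vals <- axes[[ax]]
      k <- grid[pt, ax]
      v <- vals[[k]]
      p <- apply_axis_value(p, ax, v)
      labels[[ax]] <- if (is.numeric(vals)) v else {
        if (!is.null(names(vals))) names(vals)[k] else as.character(k)
      }
    }
    p <- validate_params(p)
    ens <- run_ensemble(p, n_cells = spec$n_cells, master_seed = seeds[pt])
    ss <- steady_state_summary(ens, window = spec$window)
    point_rows[[pt]] <- cbind(
      as.data.frame(labels, stringsAsFactors = FALSE),
      summary_row(ss)
    )
    per_cell <- lapply(seq_along(ens), function(i) {
      cbind(as.data.frame(labels, stringsAsFactors = FALSE), cell_id = i,
            summary_row(steady_state_summary(ens[[i]],
                                             window = spec$window)))
    })
    cell_rows[[pt]] <- do.call(rbind, per_cell)
  }
  structure(list(points = do.call(rbind, point_rows),
                 cells = do.call(rbind, cell_rows),
                 spec = spec, master_seed = master_seed),
            class = "experiment_result")
}

summary_row <- function(ss) {
  data.frame(
    mean_health = ss$mean_health,
    p25_health = ss$p25_health,
    p75_health = ss$p75_health,
    mean_population = ss$mean_population,
    fusion_per_hr = ss$fusion_per_hr,
    frac_both = ss$motility_fractions[["both_moving"]],
    frac_one = ss$motility_fractions[["one_moving"]],
    frac_neither = ss$motility_fractions[["neither_moving"]],
    n_empty_samples = ss$n_empty_samples
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment '%s': %d grid points\n", x$spec$name,
              nrow(x$points)))
  print(x$points, digits = 3)
  invisible(x)
}

#' Built-in experiment presets
#'
#' Ready-made scan definitions for the model's standard in-silico
#' experiments. Presets are defined at full scale (25 cells, 10000 min per
#' run); pass `n_cells` and/or `t_sim` to scale them down.
#'
#' \describe{
#'   \item{`nested-models`}{four nested models: damage only; plus selective
#'     autophagy; plus replication; plus fusion/fission (the full model).}
#'   \item{`exchange-scan`}{number of HUs exchanged at fission, 0..n_HU.}
#'   \item{`threshold-grid`}{autophagy threshold x fusion threshold grid in
#'     steps of 0.1 (the health lattice at 10 HUs).}
#'   \item{`density-scan`}{filling fractions 1--55% realized by varying the
#'     cell side at fixed population.}
#'   \item{`motility-scan`}{motility scaling factors alpha and beta
#'     (beta <= alpha) crossed with the fusion rate.}
#'   \item{`cap-scan`}{trailing-window caps on autophagy events (one arm)
#'     and replication events (other arm).}
#'   \item{`discreteness-scan`}{health units per mitochondrion with the
#'     exchange count scaled proportionally (n_exchange = n_HU / 5),
#'     with fusion on and off.}
#' }
#'
#' @param name preset name (see Details).
#' @param base base parameters (default [mito_params()]).
#' @param n_cells,t_sim optional reductions of ensemble size and simulated
#'   time.
#' @return An `experiment_spec`.
#' @export
experiment_preset <- function(name, base = mito_params(), n_cells = NULL,
                              t_sim = NULL) {
  b <- unclass(base)
  if (!is.null(t_sim)) b$t_sim <- t_sim
  b <- validate_params(b)
  nc <- if (!is.null(n_cells)) n_cells else b$n_cells

  spec <- switch(
    name,
    "nested-models" = experiment_spec(
      name, b,
      axes = list(model = list(
        "damage" = list(k_aut = 0, k_rep = 0, k_fus = 0, k_fis = 0),
        "damage+autophagy" = list(k_rep = 0, k_fus = 0, k_fis = 0),
        "damage+autophagy+replication" = list(k_fus = 0, k_fis = 0),
        "full" = list()
      )),
      n_cells = nc),
    "exchange-scan" = experiment_spec(
      name, b, axes = list(n_exchange = 0:b$n_HU), n_cells = nc),
    "threshold-grid" = experiment_spec(
      name, b,
      axes = list(h_aut = seq(0.1, 0.7, by = 0.1),
                  h_fus = seq(0.1, 0.7, by = 0.1)),
      n_cells = nc),
    "density-scan" = experiment_spec(
      name, b,
      axes = list(filling_fraction = c(0.01, 0.02, 0.05, 0.10, 0.19,
                                       0.30, 0.42, 0.55)),
      n_cells = nc),
    "motility-scan" = {
      combos <- expand.grid(alpha = c(1, 0.5, 0.2),
                            beta = c(1, 0.5, 0.2, 0.05))
      combos <- combos[combos$beta <= combos$alpha, ]
      patches <- lapply(seq_len(nrow(combos)), function(i) {
        list(alpha = combos$alpha[i], beta = combos$beta[i])
      })
      names(patches) <- sprintf("a%g_b%g", combos$alpha, combos$beta)
      experiment_spec(
        name, b,
        axes = list(motility = patches, k_fus = c(0.03, 0.1, 0.3)),
        n_cells = nc)
    },
    "cap-scan" = {
      caps <- c(2, 4, 8, 16, 32, 64)
      patches <- c(
        list(uncapped = list()),
        stats::setNames(lapply(caps, function(k) list(cap_autophagy = k)),
                        sprintf("aut%d", caps)),
        stats::setNames(lapply(caps, function(k) list(cap_replication = k)),
                        sprintf("rep%d", caps))
      )
      experiment_spec(name, b, axes = list(cap = patches), n_cells = nc)
    },
    "discreteness-scan" = {
      nhu <- c(5, 10, 20, 50, 100)
      patches <- stats::setNames(
        lapply(nhu, function(k) list(n_HU = k, n_exchange = k / 5)),
        sprintf("nHU%d", nhu))
      experiment_spec(name, b,
                      axes = list(discreteness = patches,
                                  k_fus = c(0, b$k_fus)),
                      n_cells = nc)
    },
    stop("unknown experiment preset: ", name)
  )
  spec
}

#' Tiny fast configurations for testing
#'
#' Small parameter sets that preserve the model's dimensionless ratios
#' (filling fraction, rate x dt products, N0 = initial population) while
#' running in seconds.
#'
#' \describe{
#'   \item{`tiny-default`}{20 mitochondria, 500 min, full model at the
#'     default filling fraction (~0.19).}
#'   \item{`damage-only`}{as `tiny-default` but with fusion, fission,
#'     autophagy, replication, and transport switched off.}
#'   \item{`crowded`}{as `tiny-default` at 55% filling fraction.}
#' }
#'
#' @param name fixture name.
#' @return A `mito_params` object.
#' @examples
#' make_fixture("tiny-default")$n_init
#' @export
make_fixture <- function(name) {
  phi_default <- filling_fraction(150, 0.5, 25)
  tiny <- function(...) {
    base <- list(n_init = 20, t_sim = 500, n_cells = 3, N0 = 20,
                 sigma_N = 2, L = side_for_filling(20, 0.5, phi_default))
    validate_params(utils::modifyList(base, list(...)))
  }
  switch(
    name,
    "tiny-default" = tiny(),
    "damage-only" = tiny(k_fus = 0, k_fis = 0, k_aut = 0, k_rep = 0,
                         k_on = 0),
    "crowded" = tiny(L = side_for_filling(20, 0.5, 0.55)),
    stop("unknown fixture name: ", name)
  )
}

#' Calibrate filament binding/unbinding rates
#'
#' The binding rate `k_on` and unbinding rate `k_off` of the transport
#' process are not direct observables; they are calibrated by a coarse grid
#' search against the observed fusion accounting at default parameters with
#' motility scaling disabled: the overall fusion frequency (events/hr) and
#' the split of fusion events among the both-/one-/neither-moving motility
#' classes. The objective is the summed squared relative error of the four
#' observables.
#'
#' @param targets list with `fractions` (length-3 numeric, both/one/neither,
#'   summing to 1) and `events_per_hr` (positive).
#' @param p base parameters (alpha and beta are forced to 1).
#' @param k_on_grid,k_off_grid candidate rates, per minute.
#' @param n_cells,t_sim ensemble size and duration per candidate.
#' @param window steady-state window (default: final half of the run).
#' @param master_seed RNG seed.
#' @param tol_rel per-observable relative tolerance for convergence.
#' @return List with `k_on`, `k_off`, `achieved` (observables at the
#'   optimum), `objective`, `converged`, and the full `grid` data frame.
#' @export
calibrate_transport <- function(targets = list(
                                  fractions = c(0.70, 0.25, 0.05),
                                  events_per_hr = 168),
                                p = mito_params(),
                                k_on_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                                k_off_grid = c(0.025, 0.05, 0.1, 0.2),
                                n_cells = 4, t_sim = 4000, window = NULL,
                                master_seed = 1, tol_rel = 0.15) {
  stopifnot(length(targets$fractions) == 3, all(targets$fractions > 0),
            abs(sum(targets$fractions) - 1) < 1e-6,
            targets$events_per_hr > 0)
  b <- unclass(p)
  b$alpha <- 1
  b$beta <- 1
  b$t_sim <- t_sim
  if (is.null(window)) window <- c(t_sim / 2, t_sim)

  grid <- expand.grid(k_on = k_on_grid, k_off = k_off_grid)
  seeds <- derive_seeds(master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    b$k_on <- grid$k_on[g]
    b$k_off <- grid$k_off[g]
    ens <- run_ensemble(validate_params(b), n_cells = n_cells,
                        master_seed = seeds[g])
    ss <- steady_state_summary(ens, window = window)
    obs <- c(ss$motility_fractions, events_per_hr = ss$fusion_per_hr)
    tgt <- c(targets$fractions, targets$events_per_hr)
    rel <- (as.numeric(obs) - tgt) / tgt
    rows[[g]] <- data.frame(
      k_on = grid$k_on[g], k_off = grid$k_off[g],
      frac_both = obs[[1]], frac_one = obs[[2]], frac_neither = obs[[3]],
      events_per_hr = obs[[4]], objective = sum(rel^2),
      max_rel_err = max(abs(rel))
    )
  }
  res <- do.call(rbind, rows)
  best <- res[which.min(res$objective), ]
  converged <- is.finite(best$max_rel_err) && best$max_rel_err <= tol_rel
  if (!converged) {
    warning("calibration did not reach the stated tolerance; ",
            "best grid point reported")
  }
  list(k_on = best$k_on, k_off = best$k_off,
       achieved = best[, c("frac_both", "frac_one", "frac_neither",
                           "events_per_hr")],
       objective = best$objective, converged = converged, grid = res)
}
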