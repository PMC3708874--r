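#' Advance a cell by one time step
#'
#' Applies the sub-processes in fixed order — damage, transport, contact
#' detection, fusion, fission, autophagy, replication — then advances time
#' by `dt`. With per-step event probabilities of order 0.1 or less the
#' ordering bias is second order in `dt`. Identical seeds, state, and
#' parameters give bit-identical results; the composition consumes the RNG
#' stream exactly as the compiled whole-run loop used by [run()].
#'
#' @param state a `cell_state`.
#' @param p a `mito_params` object.
#' @return The updated `cell_state` (events appended to its `"events"`
#'   attribute).
#' @export
step <- function(state, p) {
  res <- cpp_step(state, p)
  append_events(carry_events(res$state, state), res$events)
}

#' Run one cell simulation
#'
#' Initializes `n_init` mitochondria at uniform non-overlapping positions
#' with each health unit independently healthy with probability 1/2, then
#' iterates [step()] for `t_sim / dt` steps, sampling summaries every
#' `record_interval` minutes.
#'
#' @param p a `mito_params` object.
#' @param seed RNG seed for this cell (integer). If `NULL`, `p$seed` is
#'   used; if that is also `NULL` the current RNG state is consumed.
#' @param log_events keep the full event log (default `TRUE`).
#' @return An object of class `mito_trajectory`: a list with elements
#' \describe{
#'   \item{samples}{data frame, one row per recorded time: `time`,
#'     `n_mito`, `mean_health`, `p25_health`, `p75_health`, `n_bonds`,
#'     `cum_autophagy`, `cum_replication`. Health summaries are `NA` when
#'     the population is empty.}
#'   \item{healths}{list of per-mitochondrion health vectors, one per
#'     sample.}
#'   \item{events}{tidy event log: `time`, `kind` (damage, fusion, fission,
#'     autophagy, replication, replication_blocked), participant ids,
#'     `motility` class for fusion, pre/post healths for fission, removed or
#'     copied health for autophagy/replication, flipped-unit counts for
#'     damage.}
#'   \item{final_state}{the final `cell_state`.}
#'   \item{params, seed}{the inputs, for provenance.}
#' }
#' @examples
#' p <- make_fixture("tiny-default")
#' tr <- run(p, seed = 1)
#' tail(tr$samples, 3)
#' @export
run <- function(p, seed = NULL, log_events = TRUE) {
  p <- validate_params(unclass(p))
  if (is.null(seed)) seed <- p$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- init_cell_state(p)
  n_steps <- as.integer(round(p$t_sim / p$dt))
  record_every <- max(1L, as.integer(round(p$record_interval / p$dt)))
  raw <- cpp_run_cell(state, p, n_steps, record_every, log_events)

  ns <- length(raw$rec_time)
  offsets <- raw$offsets
  healths <- vector("list", ns)
  for (k in seq_len(ns)) {
    idx <- seq.int(offsets[k] + 1L, length.out = offsets[k + 1L] - offsets[k])
    healths[[k]] <- raw$healths[idx]
  }
  qs <- vapply(healths, function(h) {
    if (length(h) == 0) c(NA_real_, NA_real_, NA_real_)
    else c(mean(h), stats::quantile(h, c(0.25, 0.75), names = FALSE))
  }, numeric(3))
  samples <- data.frame(
    time = raw$rec_time,
    n_mito = raw$rec_n,
    mean_health = qs[1, ],
    p25_health = qs[2, ],
    p75_health = qs[3, ],
    n_bonds = raw$rec_bonds,
    cum_autophagy = raw$rec_cum_aut,
    cum_replication = raw$rec_cum_rep
  )
  structure(list(
    samples = samples,
    healths = healths,
    events = if (log_events) tidy_events(raw$events) else empty_events(),
    final_state = raw$state,
    params = p,
    seed = seed
  ), class = "mito_trajectory")
}

#' @export
print.mito_trajectory <- function(x, ...) {
  s <- x$samples
  last <- s[nrow(s), ]
  cat(sprintf(
    "mito_trajectory: %g min simulated, %d samples\n", last$time, nrow(s)))
  cat(sprintf(
    "  final: %d mitochondria, mean health %.3f, %d bonds\n",
    last$n_mito, last$mean_health, last$n_bonds))
  cat(sprintf("  events: %d fusion, %d fission, %d autophagy, %d replication\n",
              sum(x$events$kind == "fusion"), sum(x$events$kind == "fission"),
              sum(x$events$kind == "autophagy"),
              sum(x$events$kind == "replication")))
  invisible(x)
}

#' Run an ensemble of independent cells
#'
#' Runs `n_cells` independent simulations with per-cell seeds derived
#' deterministically from the master seed, so results are reproducible and
#' independent of execution order.
#'
#' @param p a `mito_params` object.
#' @param n_cells number of cells; defaults to `p$n_cells`.
#' @param master_seed master RNG seed (integer).
#' @param log_events keep per-cell event logs (default `TRUE`).
#' @return An object of class `mito_ensemble`: a list of
#'   `mito_trajectory` with attributes `master_seed` and `cell_seeds`.
#' @examples
#' p <- make_fixture("tiny-default")
#' ens <- run_ensemble(p, n_cells = 2, master_seed = 7)
#' @export
run_ensemble <- function(p, n_cells = NULL, master_seed = 1,
                         log_events = TRUE) {
  p <- validate_params(unclass(p))
  if (is.null(n_cells)) n_cells <- p$n_cells
  stopifnot(n_cells >= 1)
  seeds <- derive_seeds(master_seed, n_cells)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    out[[i]] <- run(p, seed = seeds[i], log_events = log_events)
  }
  structure(out, class = "mito_ensemble",
            master_seed = master_seed, cell_seeds = seeds)
}

# deterministic stream of distinct per-cell seeds from one master seed
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' @export
print.mito_ensemble <- function(x, ...) {
  cat(sprintf("mito_ensemble: %d cells, master seed %s\n",
              length(x), format(attr(x, "master_seed"))))
  invisible(x)
}

#' Tidy table of trajectory samples
#'
#' @param x a `mito_trajectory` or `mito_ensemble`.
#' @return A data frame with one row per cell per sample: `cell_id`,
#'   `time`, `n_mito`, `mean_health`, `p25_health`, `p75_health`,
#'   `n_bonds`, `cum_autophagy`, `cum_replication`.
#' @export
trajectory_table <- function(x) {
  if (inherits(x, "mito_trajectory")) x <- list(x)
  out <- lapply(seq_along(x), function(i) {
    cbind(cell_id = i, x[[i]]$samples)
  })
  do.call(rbind, out)
}
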