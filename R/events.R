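#' @name quality_control_events
#' @title Stochastic quality-control processes
#'
#' @description
#' The six stochastic sub-processes applied to a cell each time step:
#' oxidative damage to health units, selective fusion of touching pairs,
#' fission with discrete health-unit exchange, selective autophagy of
#' unfused sub-threshold mitochondria, and population-limited replication.
#' Each `*_step()` function consumes R's RNG stream and returns the updated
#' [cell_state()]; any events generated are appended to the state's
#' `"events"` attribute as tidy rows (see [run()] for column documentation).
#'
#' Per-step probabilities follow the usual exponential discretization of a
#' constant-rate Poisson process: an event of rate `k` occurs within one
#' step of length `dt` with probability `1 - exp(-k * dt)`.
NULL

append_events <- function(state, evdf) {
  old <- attr(state, "events")
  ev <- tidy_events(evdf)
  attr(state, "events") <- if (is.null(old)) ev else rbind(old, ev)
  state
}

carry_events <- function(new_state, old_state) {
  attr(new_state, "events") <- attr(old_state, "events")
  new_state
}

#' @rdname quality_control_events
#' @details `damage_step()`: every healthy HU in every mitochondrion flips
#' to the damaged state independently with probability
#' `1 - exp(-k_damage * dt)`; damaged units never recover.
#' @param state a `cell_state`.
#' @param p a `mito_params` object.
#' @return The updated `cell_state`.
#' @export
damage_step <- function(state, p) {
  res <- cpp_damage_step(state, p)
  append_events(carry_events(res$state, state), res$events)
}

#' @rdname quality_control_events
#' @details `fusion_step()`: each touching pair whose members both have
#' health at or above `h_fus` fuses with probability
#' `s * (1 - exp(-k_fus * dt))`, where the scale `s` is 1, `alpha`, or
#' `beta` according to whether both, one, or neither partner was moving at
#' contact. Fusing adds a bond (networks of more than two mitochondria arise
#' from repeated fusion) and immobilizes both partners.
#' @param contact_graph a data frame from [contacts()] for the current
#'   positions (columns `id1`, `id2`, `class`).
#' @export
fusion_step <- function(state, contact_graph, p) {
  cls <- contact_graph$class
  if (is.factor(cls) || is.character(cls)) {
    cls <- match(as.character(cls), motility_levels()) - 1L
  }
  res <- cpp_fusion_step(state, p, as.integer(contact_graph$id1),
                         as.integer(contact_graph$id2), as.integer(cls))
  append_events(carry_events(res$state, state), res$events)
}

#' @rdname quality_control_events
#' @details `fission_step()`: each fusion bond breaks independently with
#' probability `1 - exp(-k_fis * dt)`; at each break, `n_exchange` randomly
#' chosen health units are swapped between the two endpoint mitochondria
#' ([exchange_units()]), conserving the total number of healthy units.
#' Mitochondria left without bonds become independent, stationary, and
#' unbound from any filament.
#' @export
fission_step <- function(state, p) {
  res <- cpp_fission_step(state, p)
  append_events(carry_events(res$state, state), res$events)
}

#' @rdname quality_control_events
#' @details `autophagy_step()`: each unfused mitochondrion with health
#' strictly below `h_aut` is removed with probability
#' `1 - exp(-k_aut * dt)`, subject to the trailing-window cap
#' `cap_autophagy` (see [window_allows()]). Fused mitochondria are never
#' removed: the autophagosome size limit is taken to be a single unfused
#' mitochondrion.
#' @export
autophagy_step <- function(state, p) {
  res <- cpp_autophagy_step(state, p)
  append_events(carry_events(res$state, state), res$events)
}

#' @rdname quality_control_events
#' @details `replicate_step()`: with probability
#' `1 - exp(-N * replication_rate(N, p) * dt)` (at most one event per step),
#' a uniformly chosen mitochondrion is copied: the daughter has the same
#' health-unit vector, a new id, is stationary and unfused, and is placed
#' uniformly at random without overlap. Subject to `cap_replication`. If no
#' non-overlapping position is found within the attempt budget the event is
#' skipped and logged as `replication_blocked`.
#' @export
replicate_step <- function(state, p) {
  res <- cpp_replicate_step(state, p)
  append_events(carry_events(res$state, state), res$events)
}

#' Population-limited replication rate
#'
#' Per-mitochondrion replication rate `k_rep * g(N)` with the population
#' cutoff `g(N) = 1 / (1 + exp((N - N0) / sigma_N))`: monotone
#' non-increasing in the population size `N`, approximately `k_rep` for
#' `N << N0`, `k_rep / 2` at `N = N0`, and asymptotically zero as `N`
#' grows. The logistic form is isolated here so alternative cutoffs with
#' the same asymptotics can be swapped in.
#'
#' @param N population size (number of mitochondria).
#' @param p a `mito_params` object (uses `k_rep`, `N0`, `sigma_N`).
#' @return Per-mitochondrion rate, per minute.
#' @examples
#' p <- mito_params()
#' replication_rate(p$N0, p) # k_rep / 2
#' @export
replication_rate <- function(N, p) {
  stopifnot(all(N >= 0))
  vapply(N, function(n) p$k_rep * cpp_replication_g(n, p$N0, p$sigma_N),
         numeric(1))
}

#' Exchange health units between two mitochondria
#'
#' Chooses `n` unit positions uniformly without replacement, independently
#' in `a` and in `b`, and swaps the chosen unit states pairwise. The total
#' number of healthy units is conserved; exchanging `n` units is
#' statistically equivalent to exchanging `length(a) - n` units up to
#' relabeling of the two partners.
#'
#' @param a,b 0/1 vectors of equal length (health-unit states).
#' @param n number of units to exchange, `0 <= n <= length(a)`.
#' @return A list with the post-exchange vectors `a` and `b`.
#' @examples
#' set.seed(1)
#' exchange_units(rep(1, 10), rep(0, 10), 2)
#' @export
exchange_units <- function(a, b, n) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (n < 0 || n > length(a)) {
    stop("n must satisfy 0 <= n <= length(a)")
  }
  a <- as.integer(a)
  b <- as.integer(b)
  if (any(is.na(a)) || any(is.na(b)) || !all(c(a, b) %in% c(0L, 1L))) {
    stop("a and b must contain only 0/1 unit states")
  }
  cpp_exchange_units(a, b, as.integer(n))
}

#' Trailing-window event cap
#'
#' Returns `TRUE` if another event is allowed now: the number of event
#' timestamps in the trailing 180-minute window `(now - 180, now]` is
#' strictly below `cap`. An infinite cap always allows; the restriction
#' lifts automatically as old events age out of the window.
#'
#' @param times sorted numeric vector of past event times, minutes.
#' @param cap maximum events per window (`Inf` = unlimited).
#' @param now current time, minutes.
#' @return Logical.
#' @examples
#' window_allows(c(10, 50, 90), cap = 3, now = 100)  # FALSE
#' window_allows(c(10, 50, 90), cap = 3, now = 200)  # TRUE (10, 50 aged out)
#' @export
window_allows <- function(times, cap, now) {
  stopifnot(!is.unsorted(times))
  cpp_window_allows(as.numeric(times), as.numeric(cap), as.numeric(now))
}
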