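#' Steady-state summary over a time window
#'
#' Time-and-ensemble averages over all samples whose time falls inside the
#' window: mean and 25th/75th-percentile health over the pooled
#' per-mitochondrion healths, mean population size, fusion-event frequency,
#' and the motility-class split of fusion events. Samples from empty cells
#' contribute a single health of 0 and are flagged via `n_empty_samples`.
#'
#' @param x a `mito_trajectory` or `mito_ensemble`.
#' @param window numeric length-2 vector `c(start, end)` in minutes;
#'   defaults to the final 2000 minutes of the simulated span.
#' @return An object of class `steady_state_summary`: a list with
#'   `window`, `mean_health`, `p25_health`, `p75_health`,
#'   `mean_population`, `fusion_per_hr`, `motility_fractions` (named:
#'   both_moving, one_moving, neither_moving), `n_fusion_events`,
#'   `n_samples`, `n_empty_samples`, `n_cells`.
#' @examples
#' p <- make_fixture("tiny-default")
#' tr <- run(p, seed = 1)
#' steady_state_summary(tr, window = c(250, 500))
#' @export
steady_state_summary <- function(x, window = NULL) {
  trajs <- if (inherits(x, "mito_trajectory")) list(x) else x
  span <- range(trajs[[1]]$samples$time)
  if (is.null(window)) window <- c(max(span[1], span[2] - 2000), span[2])
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < span[1] || window[2] > span[2]) {
    stop("window must lie within the simulated span [",
         span[1], ", ", span[2], "]")
  }

  pooled <- numeric(0)
  pops <- numeric(0)
  n_empty <- 0L
  n_samples <- 0L
  for (tr in trajs) {
    sel <- which(tr$samples$time >= window[1] & tr$samples$time <= window[2])
    n_samples <- n_samples + length(sel)
    for (k in sel) {
      h <- tr$healths[[k]]
      if (length(h) == 0) {
        n_empty <- n_empty + 1L
        pooled <- c(pooled, 0) # empty cell counts as health collapse
      } else {
        pooled <- c(pooled, h)
      }
    }
    pops <- c(pops, tr$samples$n_mito[sel])
  }
  if (n_samples == 0) stop("window contains no recorded samples")

  ff <- fusion_frequency(do.call(rbind, lapply(trajs, `[[`, "events")),
                         window, n_cells = length(trajs))
  structure(list(
    window = window,
    mean_health = mean(pooled),
    p25_health = stats::quantile(pooled, 0.25, names = FALSE),
    p75_health = stats::quantile(pooled, 0.75, names = FALSE),
    mean_population = mean(pops),
    fusion_per_hr = ff$events_per_hr,
    motility_fractions = ff$motility_fractions,
    n_fusion_events = ff$n_events,
    n_samples = n_samples,
    n_empty_samples = n_empty,
    n_cells = length(trajs)
  ), class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf("steady-state window [%g, %g] min over %d cell(s)\n",
              x$window[1], x$window[2], x$n_cells))
  cat(sprintf("  mean health %.3f (p25 %.3f, p75 %.3f), mean population %.1f\n",
              x$mean_health, x$p25_health, x$p75_health, x$mean_population))
  cat(sprintf("  fusion %.1f events/hr per cell (%d events)\n",
              x$fusion_per_hr, x$n_fusion_events))
  if (!all(is.na(x$motility_fractions))) {
    cat(sprintf("  motility split both/one/neither: %.2f / %.2f / %.2f\n",
                x$motility_fractions[1], x$motility_fractions[2],
                x$motility_fractions[3]))
  }
  if (x$n_empty_samples > 0) {
    cat(sprintf("  note: %d empty-cell samples contributed health 0\n",
                x$n_empty_samples))
  }
  invisible(x)
}

#' Fusion-event frequency and motility-class split
#'
#' Counts fusion records inside the window and divides by the window length
#' in hours (per cell when `n_cells > 1`), and reports the fraction of
#' events in each motility class (both, one, or neither partner moving at
#' contact). With no fusion events the fractions are `NA` and flagged.
#'
#' @param events an event-log data frame (or several row-bound together).
#' @param window numeric `c(start, end)`, minutes. Events with
#'   `start <= time <= end` are counted.
#' @param n_cells number of cells whose logs were pooled (divisor for the
#'   per-cell frequency).
#' @return List with `events_per_hr`, `motility_fractions` (named numeric,
#'   `NA` if no events), `n_events`, and `window`.
#' @examples
#' log <- data.frame(time = seq(1, 30, length.out = 84), kind = "fusion",
#'                   motility = "both_moving")
#' fusion_frequency(log, c(0, 30))$events_per_hr # 168
#' @export
fusion_frequency <- function(events, window, n_cells = 1) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("window must have positive length")
  hours <- (window[2] - window[1]) / 60
  fus <- events[events$kind == "fusion" &
                  events$time >= window[1] & events$time <= window[2], ,
                drop = FALSE]
  n <- nrow(fus)
  fracs <- if (n == 0) {
    stats::setNames(rep(NA_real_, 3), motility_levels())
  } else {
    tab <- table(factor(fus$motility, levels = motility_levels()))
    stats::setNames(as.numeric(tab) / n, motility_levels())
  }
  list(events_per_hr = n / hours / n_cells,
       motility_fractions = fracs,
       n_events = n,
       window = window)
}

#' Locate the density transition in a filling-fraction scan
#'
#' The transition from fragmented mitochondria to extended fused networks
#' is identified as the steepest rise of the fusion-event frequency along
#' the density axis: the largest difference quotient between consecutive
#' grid points, attributed to the upper point of the pair.
#'
#' @param phi filling fractions (ascending).
#' @param fusion_per_hr fusion-event frequencies at those densities.
#' @return The filling fraction at the steepest rise.
#' @export
density_transition <- function(phi, fusion_per_hr) {
  stopifnot(length(phi) == length(fusion_per_hr), length(phi) >= 2,
            !is.unsorted(phi))
  slopes <- diff(fusion_per_hr) / diff(phi)
  phi[which.max(slopes) + 1L]
}

#' Connected components of the fusion or contact graph
#'
#' Component sizes of either the fusion-bond graph (`mode = "fused"`) or the
#' contact graph of touching mitochondria regardless of fusion state
#' (`mode = "contact"`). Fused components are always refinements of contact
#' components, since bonds only form between touching pairs that then stop
#' moving. Components are computed by union-find.
#'
#' @param state a `cell_state`.
#' @param mode `"fused"` or `"contact"`.
#' @param p a `mito_params` object; required for `mode = "contact"`
#'   (contact radius and tolerance).
#' @return A list with `membership` (integer component label per
#'   mitochondrion, named by id), `sizes` (component sizes), and
#'   `histogram` (table of component-size counts).
#' @export
components <- function(state, mode = c("fused", "contact"), p = NULL) {
  mode <- match.arg(mode)
  ids <- state$id
  n <- length(ids)
  if (mode == "fused") {
    edges <- state$bonds
  } else {
    if (is.null(p)) stop("mode = 'contact' requires the parameter set p")
    cg <- contacts(state, p)
    edges <- cbind(cg$id1, cg$id2)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    ei <- match(edges[, 1], ids)
    ej <- match(edges[, 2], ids)
    for (k in seq_along(ei)) {
      ri <- find(ei[k])
      rj <- find(ej[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, unique(roots))
  sizes <- as.integer(table(membership))
  list(membership = stats::setNames(membership, ids),
       sizes = sizes,
       histogram = table(sizes))
}

#' Health histogram on the discrete health lattice
#'
#' Normalized distribution of per-mitochondrion healths with bins centered
#' on the lattice `{0, 1/n_HU, ..., 1}` (bin width `1/n_HU` by default, or
#' an integer multiple of it).
#'
#' @param healths numeric vector of healths, or a `mito_trajectory` /
#'   `mito_ensemble` (pooled over samples in `window`).
#' @param n_HU number of health units (sets the lattice).
#' @param bin_width bin width; must be an integer multiple of `1 / n_HU`.
#' @param window optional time window when `healths` is a trajectory or
#'   ensemble (defaults to the final 2000 minutes).
#' @return Data frame with `mid` (bin center), `count`, and `mass`
#'   (normalized to sum to 1).
#' @export
health_histogram <- function(healths, n_HU = 10, bin_width = 1 / n_HU,
                             window = NULL) {
  if (inherits(healths, "mito_trajectory") ||
      inherits(healths, "mito_ensemble")) {
    trajs <- if (inherits(healths, "mito_trajectory")) list(healths) else
      healths
    n_HU <- trajs[[1]]$params$n_HU
    if (missing(bin_width)) bin_width <- 1 / n_HU
    span <- range(trajs[[1]]$samples$time)
    if (is.null(window)) window <- c(max(span[1], span[2] - 2000), span[2])
    healths <- unlist(lapply(trajs, function(tr) {
      sel <- tr$samples$time >= window[1] & tr$samples$time <= window[2]
      unlist(tr$healths[sel])
    }))
  }
  k <- bin_width * n_HU
  if (abs(k - round(k)) > 1e-9) {
    stop("bin_width must be an integer multiple of 1/n_HU")
  }
  breaks <- seq(-bin_width / 2, 1 + bin_width / 2, by = bin_width)
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  counts <- as.integer(
    table(cut(healths, breaks = breaks, include.lowest = TRUE)))
  data.frame(mid = mids, count = counts,
             mass = if (sum(counts) > 0) counts / sum(counts) else
               rep(0, length(counts)))
}
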