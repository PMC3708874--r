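#' Area filling fraction of the mitochondrial population
#'
#' Total mitochondrial cross-sectional area divided by cell area,
#' `n * pi * r^2 / L^2`.
#'
#' @param n number of mitochondria.
#' @param r mitochondrion radius, um.
#' @param L cell side length, um.
#' @return Filling fraction (dimensionless).
#' @examples
#' filling_fraction(150, 0.5, 25) # ~0.188
#' @export
filling_fraction <- function(n, r, L) {
  stopifnot(L > 0, r >= 0, n >= 0)
  n * pi * r^2 / L^2
}

#' Cell side length realizing a target filling fraction
#'
#' Density scans vary the cell size at fixed population, so the side length
#' for a target filling fraction `phi` is `sqrt(n * pi * r^2 / phi)`.
#'
#' @param n number of mitochondria.
#' @param r mitochondrion radius, um.
#' @param phi target filling fraction in (0, 1).
#' @return Cell side length, um.
#' @examples
#' side_for_filling(150, 0.5, 0.55)
#' @export
side_for_filling <- function(n, r, phi) {
  stopifnot(phi > 0, phi < 1, n > 0, r > 0)
  sqrt(n * pi * r^2 / phi)
}

#' Place mitochondria uniformly without overlap
#'
#' Rejection-samples `n` centers uniformly in `[r, L - r]^2` such that all
#' pairwise center distances are at least `2 r` (hard disks). Exceeding the
#' per-mitochondrion attempt budget raises an infeasible-packing error that
#' names the filling fraction.
#'
#' @param n number of mitochondria.
#' @param L cell side length, um.
#' @param r mitochondrion radius, um.
#' @param max_attempts rejection budget per mitochondrion.
#' @return An `n` x 2 matrix of centers (columns `x`, `y`).
#' @examples
#' set.seed(1)
#' pos <- place_non_overlapping(50, 25, 0.5)
#' min(dist(pos)) >= 1
#' @export
place_non_overlapping <- function(n, L, r, max_attempts = 1e5) {
  stopifnot(n >= 0, L > 2 * r, r > 0, max_attempts >= 1)
  phi <- filling_fraction(n, r, L)
  if (phi > 0.9) {
    stop(sprintf(
      "infeasible packing: filling fraction %.3f exceeds 0.9", phi))
  }
  if (n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  cpp_place(as.integer(n), L, r, as.integer(max_attempts))
}

#' Advance transport by one time step
#'
#' Persistent-random-walk transport along implicit cytoskeletal filaments:
#' each stationary unfused mitochondrion binds a filament with probability
#' `1 - exp(-k_on * dt)` (direction uniform on \[0, 2 pi)); each moving one
#' unbinds with probability `1 - exp(-k_off * dt)`; each still-moving one
#' advances `v * dt` along its direction, truncated at the first contact with
#' another mitochondrion (center distance `2 r`) or at the cell wall, either
#' of which detaches it from its filament. Fused mitochondria never move.
#' Movers are advanced in random order; earlier movers are obstacles for
#' later ones.
#'
#' @param state a `cell_state`.
#' @param p a `mito_params` object.
#' @return The updated `cell_state` (the `moved` field records which
#'   mitochondria were in motion during this sub-step; [contacts()] uses it
#'   to classify pair motility).
#' @export
transport_step <- function(state, p) {
  cpp_transport_step(state, p)
}

#' Contact graph of touching mitochondria
#'
#' All unordered pairs whose center distance is at most `2 r + tol`,
#' annotated with the motility class observed in the transport sub-step
#' just completed: whether both, exactly one, or neither member was in
#' motion (fused network members count as not moving). The result equals
#' the brute-force scan over all pairs.
#'
#' @param state a `cell_state`.
#' @param p a `mito_params` object (supplies `r` and, by default, `tol`).
#' @param tol contact tolerance in um; defaults to `p$tol`.
#' @return A data frame with columns `id1`, `id2` (mitochondrion ids) and
#'   `class` (factor: `both_moving`, `one_moving`, `neither_moving`).
#' @export
contacts <- function(state, p, tol = p$tol) {
  p2 <- unclass(p)
  p2$tol <- tol
  df <- cpp_contacts(state, p2)
  df$class <- factor(motility_levels()[df$class + 1L],
                     levels = motility_levels())
  df
}

motility_levels <- function() c("both_moving", "one_moving", "neither_moving")

# Dense placement on a jittered triangular lattice. Uniform rejection
# sampling jams near a filling fraction of ~0.55 (random sequential
# addition limit for disks), so initializations above ~0.45 use the
# densest-packing lattice with the largest spacing that fits n sites,
# each site jittered uniformly within half its clearance. Site order is
# randomized so the occupied subset is random.
place_lattice_jitter <- function(n, L, r) {
  stopifnot(n >= 1, L > 2 * r)
  fits <- function(a) {
    dy <- a * sqrt(3) / 2
    ny <- floor((L - 2 * r) / dy) + 1
    nx <- floor((L - 2 * r) / a) + 1
    # odd rows are offset by a/2 and may lose their last site
    total <- 0
    for (row in seq_len(ny) - 1) {
      width <- (L - 2 * r) - (row %% 2) * a / 2
      total <- total + max(0, floor(width / a) + 1)
    }
    total
  }
  lo <- 2 * r
  hi <- L
  if (fits(lo) < n) stop("infeasible packing even on a triangular lattice")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (fits(mid) >= n) lo <- mid else hi <- mid
  }
  a <- lo
  dy <- a * sqrt(3) / 2
  ny <- floor((L - 2 * r) / dy) + 1
  sites <- NULL
  for (row in seq_len(ny) - 1) {
    x0 <- r + (row %% 2) * a / 2
    nx <- max(0, floor(((L - 2 * r) - (row %% 2) * a / 2) / a) + 1)
    if (nx > 0) {
      sites <- rbind(sites, cbind(x0 + a * (seq_len(nx) - 1),
                                  r + dy * row))
    }
  }
  stopifnot(nrow(sites) >= n)
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  jmax <- 0.45 * (a - 2 * r) # min pair distance stays >= 0.1*a + 1.8*r >= 2r
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- jmax * sqrt(stats::runif(n))
  pos <- cbind(x = pmin(pmax(sites[, 1] + rad * cos(ang), r), L - r),
               y = pmin(pmax(sites[, 2] + rad * sin(ang), r), L - r))
  pos
}
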