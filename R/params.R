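#' Simulation parameters
#'
#' Construct the full parameter set of the quality-control model. Defaults
#' are the typical values used throughout: a 25 x 25 um square cell seeded
#' with 150 circular mitochondria of radius 0.5 um, each carrying 10 binary
#' health units (HUs), with per-HU oxidative damage, contact-limited selective
#' fusion, fission with exchange of 2 randomly chosen HUs, selective autophagy
#' of unfused sub-threshold mitochondria, and population-limited replication.
#'
#' @param dt time step, minutes.
#' @param t_sim total simulated time, minutes.
#' @param n_cells default ensemble size (independent simulated cells).
#' @param n_init initial number of mitochondria per cell.
#' @param L cell side length, micrometres.
#' @param r mitochondrion radius, micrometres.
#' @param k_damage damage rate per healthy HU, per minute.
#' @param k_fus fusion rate for a touching eligible pair, per minute.
#' @param k_fis fission rate per fusion bond, per minute.
#' @param k_aut autophagy rate per eligible mitochondrion, per minute.
#' @param k_rep replication rate scale per mitochondrion, per minute.
#' @param N0 typical population size in the replication rate limit.
#' @param sigma_N width of the population-size replication cutoff.
#' @param h_aut autophagy threshold (health fraction); mitochondria strictly
#'   below it are eligible for removal.
#' @param h_fus fusion threshold (health fraction); both partners must be at
#'   or above it to fuse.
#' @param n_HU number of health units per mitochondrion.
#' @param n_exchange number of HUs exchanged between the two partners at each
#'   fission event.
#' @param v transport speed along cytoskeletal filaments, um per minute.
#' @param k_on filament binding rate, per minute (calibrated, with `k_off`,
#'   against the observed motility-class split of fusion events; see the
#'   methods vignette).
#' @param k_off filament unbinding rate, per minute.
#' @param alpha fusion probability scale when exactly one partner was moving
#'   at contact (dimensionless, <= 1).
#' @param beta fusion probability scale when neither partner was moving
#'   (dimensionless, <= alpha).
#' @param cap_autophagy maximum autophagy events per trailing 180-minute
#'   window (`Inf` = unlimited).
#' @param cap_replication maximum replication events per trailing 180-minute
#'   window (`Inf` = unlimited).
#' @param tol contact tolerance, micrometres: centers within `2*r + tol`
#'   count as touching.
#' @param record_interval trajectory sampling interval, minutes.
#' @param max_place_attempts rejection-sampling budget per mitochondrion when
#'   placing without overlap.
#' @param seed optional default RNG seed used by [run()] when none is given.
#'
#' @return A validated object of class `mito_params` (a named list).
#' @seealso [validate_params()], [read_config()], [write_config()]
#' @examples
#' p <- mito_params()
#' p$k_fus
#' p2 <- mito_params(n_exchange = 5)
#' @export
mito_params <- function(dt = 1,
                        t_sim = 10000,
                        n_cells = 25,
                        n_init = 150,
                        L = 25,
                        r = 0.5,
                        k_damage = 5e-4,
                        k_fus = 0.1,
                        k_fis = 0.1,
                        k_aut = 3.33e-3,
                        k_rep = 0.02,
                        N0 = 150,
                        sigma_N = 15,
                        h_aut = 0.3,
                        h_fus = 0.3,
                        n_HU = 10,
                        n_exchange = 2,
                        v = 0.5,
                        k_on = 8,
                        k_off = 0.002,
                        alpha = 1,
                        beta = 1,
                        cap_autophagy = Inf,
                        cap_replication = Inf,
                        tol = 0.01,
                        record_interval = 10,
                        max_place_attempts = 1e5,
                        seed = NULL) {
  p <- list(
    dt = dt, t_sim = t_sim, n_cells = n_cells, n_init = n_init, L = L, r = r,
    k_damage = k_damage, k_fus = k_fus, k_fis = k_fis, k_aut = k_aut,
    k_rep = k_rep, N0 = N0, sigma_N = sigma_N, h_aut = h_aut, h_fus = h_fus,
    n_HU = n_HU, n_exchange = n_exchange, v = v, k_on = k_on, k_off = k_off,
    alpha = alpha, beta = beta, cap_autophagy = cap_autophagy,
    cap_replication = cap_replication, tol = tol,
    record_interval = record_interval,
    max_place_attempts = max_place_attempts, seed = seed
  )
  validate_params(p)
}

#' Validate and normalize a parameter set
#'
#' Fills defaults for missing fields, coerces numeric types, and checks every
#' model invariant (non-negative rates, thresholds in \[0, 1\], exchange count
#' bounded by the number of health units, `beta <= alpha <= 1`, and a feasible
#' initial packing). Violations are reported together, one message per field.
#'
#' @param p a named list of parameters (any subset of the fields of
#'   [mito_params()]).
#' @return A complete object of class `mito_params`.
#' @examples
#' validate_params(list(k_fus = 0.2))$k_fus
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  defaults <- formals(mito_params)
  fields <- names(defaults)
  unknown <- setdiff(names(p), fields)
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  out <- lapply(fields, function(f) {
    if (!is.null(p[[f]])) p[[f]] else eval(defaults[[f]])
  })
  names(out) <- fields

  num_fields <- setdiff(fields, "seed")
  for (f in num_fields) {
    v <- out[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop(sprintf("parameter '%s' must be a single non-missing number", f))
    }
    out[[f]] <- as.numeric(v)
  }

  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)

  for (f in c("dt", "v")) {
    chk(out[[f]] > 0, sprintf("%s must be > 0", f))
  }
  for (f in c("t_sim", "k_damage", "k_fus", "k_fis", "k_aut", "k_rep",
              "k_on", "k_off", "sigma_N", "N0")) {
    chk(out[[f]] >= 0, sprintf("%s must be >= 0", f))
  }
  chk(out$sigma_N > 0, "sigma_N must be > 0")
  chk(out$n_cells >= 1, "n_cells must be >= 1")
  chk(out$n_init >= 0, "n_init must be >= 0")
  chk(out$h_aut >= 0 && out$h_aut <= 1, "h_aut must be in [0, 1]")
  chk(out$h_fus >= 0 && out$h_fus <= 1, "h_fus must be in [0, 1]")
  chk(out$n_HU >= 1 && out$n_HU == round(out$n_HU),
      "n_HU must be a positive integer")
  chk(out$n_exchange >= 0 && out$n_exchange == round(out$n_exchange),
      "n_exchange must be a non-negative integer")
  chk(out$n_exchange <= out$n_HU, "n_exchange must be <= n_HU")
  chk(out$alpha >= 0 && out$alpha <= 1, "alpha must be in [0, 1]")
  chk(out$beta >= 0 && out$beta <= out$alpha,
      "beta must satisfy 0 <= beta <= alpha")
  chk(out$r > 0, "r must be > 0")
  chk(out$L > 2 * out$r, "L must exceed the mitochondrion diameter 2*r")
  chk(out$cap_autophagy >= 0, "cap_autophagy must be >= 0 (Inf = unlimited)")
  chk(out$cap_replication >= 0,
      "cap_replication must be >= 0 (Inf = unlimited)")
  chk(out$tol >= 0, "tol must be >= 0")
  chk(out$record_interval > 0, "record_interval must be > 0")
  chk(out$max_place_attempts >= 1, "max_place_attempts must be >= 1")
  if (out$r > 0 && out$L > 0) {
    phi <- filling_fraction(out$n_init, out$r, out$L)
    chk(phi < 0.9, sprintf(
      "initial packing infeasible: filling fraction %.3f exceeds 0.9", phi))
  }
  if (length(errs) > 0) {
    stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "))
  }

  for (f in c("n_cells", "n_init", "n_HU", "n_exchange",
              "max_place_attempts")) {
    out[[f]] <- as.integer(round(out[[f]]))
  }
  if (!is.null(out$seed)) out$seed <- as.integer(out$seed)
  structure(out, class = "mito_params")
}

#' @export
print.mito_params <- function(x, ...) {
  cat("Mitochondrial quality-control model parameters\n")
  cat(sprintf("  cell %g x %g um, %d mitochondria of radius %g um (phi = %.3f)\n",
              x$L, x$L, x$n_init, x$r, filling_fraction(x$n_init, x$r, x$L)))
  cat(sprintf("  %d HUs per mitochondrion, %d exchanged at fission\n",
              x$n_HU, x$n_exchange))
  cat(sprintf("  rates [1/min]: damage %.2g, fusion %.2g, fission %.2g, autophagy %.2g, replication %.2g\n",
              x$k_damage, x$k_fus, x$k_fis, x$k_aut, x$k_rep))
  cat(sprintf("  thresholds: autophagy %.2f, fusion %.2f\n", x$h_aut, x$h_fus))
  cat(sprintf("  transport: v %.2g um/min, k_on %.2g, k_off %.2g; motility scaling alpha %.2g, beta %.2g\n",
              x$v, x$k_on, x$k_off, x$alpha, x$beta))
  cat(sprintf("  caps per 180 min: autophagy %s, replication %s\n",
              format(x$cap_autophagy), format(x$cap_replication)))
  cat(sprintf("  t_sim %g min, dt %g min, ensemble %d cells\n",
              x$t_sim, x$dt, x$n_cells))
  invisible(x)
}

#' Health of a mitochondrion
#'
#' The health of a mitochondrion is the fraction of its discrete health units
#' (HUs) that are in the undamaged state: `sum(hu) / length(hu)`. It is the
#' model's proxy for the inner-membrane potential of the organelle.
#'
#' @param hu logical or 0/1 vector of health-unit states (1 = healthy).
#' @return Health fraction in \[0, 1\].
#' @examples
#' mito_health(rep(1, 10))           # 1.0
#' mito_health(c(rep(1, 7), rep(0, 3))) # 0.7
#' @export
mito_health <- function(hu) {
  if (length(hu) == 0) stop("hu must be a non-empty vector of unit states")
  hu <- as.numeric(hu)
  if (any(is.na(hu)) || !all(hu %in% c(0, 1))) {
    stop("hu must contain only 0/1 (or FALSE/TRUE) unit states")
  }
  sum(hu) / length(hu)
}

# fields serialized to config files (seed included when set)
config_fields <- function() {
  setdiff(names(formals(mito_params)), character(0))
}

#' Read a parameter configuration file
#'
#' Configurations are flat `key: value` text (YAML syntax) whose keys are the
#' field names of [mito_params()]. Missing keys take their defaults; unknown
#' keys are an error. `.inf` denotes an unlimited cap.
#'
#' @param path file path.
#' @param overrides optional character vector of `key=value` overrides
#'   (applied after the file, e.g. from a command line `--set`).
#' @return A validated `mito_params` object.
#' @export
read_config <- function(path, overrides = character(0)) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must have the form key=value: ", ov)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    raw[[key]] <- if (tolower(val) %in% c("inf", ".inf")) Inf else
      as.numeric(val)
  }
  validate_params(raw)
}

#' Write a parameter configuration file
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces every field bit-exactly.
#'
#' @param p a `mito_params` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  p <- validate_params(unclass(p))
  lines <- character(0)
  for (f in config_fields()) {
    v <- p[[f]]
    if (is.null(v)) next
    txt <- if (is.infinite(v)) ".inf" else sprintf("%.17g", as.numeric(v))
    lines <- c(lines, paste0(f, ": ", txt))
  }
  writeLines(lines, path)
  invisible(path)
}
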