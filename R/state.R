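#' Construct a cell state
#'
#' A `cell_state` holds the full microstate of one simulated cell: positions,
#' health-unit matrices, motion states, the fusion-bond graph (as id pairs),
#' elapsed time, and the trailing-window event counters used by the autophagy
#' and replication rate caps.
#'
#' @param pos n x 2 matrix of centers (um).
#' @param hu n x n_HU 0/1 matrix of health-unit states (1 = healthy).
#' @param time elapsed time, minutes.
#' @param motion integer vector, 0 = stationary, 1 = moving.
#' @param theta direction of motion, radians (ignored while stationary).
#' @param bonds m x 2 integer matrix of fused id pairs.
#' @param id integer mitochondrion ids (unique, persistent).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(pos, hu, time = 0, motion = NULL, theta = NULL,
                       bonds = NULL, id = NULL) {
  pos <- as.matrix(pos)
  hu <- as.matrix(hu)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 2, nrow(hu) == n)
  storage.mode(hu) <- "integer"
  if (any(is.na(hu)) || !all(hu %in% c(0L, 1L))) {
    stop("hu matrix must contain only 0/1 states")
  }
  if (is.null(motion)) motion <- rep(0L, n)
  if (is.null(theta)) theta <- rep(0, n)
  if (is.null(id)) id <- seq_len(n)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && !all(bonds %in% id)) {
    stop("bonds may only connect existing mitochondrion ids")
  }
  deg <- tabulate(match(c(bonds), id), nbins = n)
  if (any(deg > 0 & as.integer(motion) == 1L)) {
    stop("fused mitochondria must be stationary")
  }
  colnames(pos) <- c("x", "y")
  structure(list(
    time = as.numeric(time),
    pos = pos,
    hu = hu,
    motion = as.integer(motion),
    theta = as.numeric(theta),
    moved = rep(0L, n),
    id = as.integer(id),
    next_id = if (n > 0) max(as.integer(id)) + 1L else 1L,
    bonds = bonds,
    aut_times = numeric(0),
    rep_times = numeric(0),
    cum_autophagy = 0L,
    cum_replication = 0L
  ), class = "cell_state")
}

#' Initialize a cell state from parameters
#'
#' Places `n_init` mitochondria uniformly at random without overlap and draws
#' each health unit independently healthy with probability 1/2, so the
#' initial population health is distributed Binomial(`n_HU`, 1/2)/`n_HU`
#' with mean 0.5. All mitochondria start stationary and unfused.
#'
#' @param p a `mito_params` object.
#' @return A `cell_state` at time 0.
#' @export
init_cell_state <- function(p) {
  phi <- filling_fraction(p$n_init, p$r, p$L)
  pos <- if (phi > 0.45 && p$n_init > 0) {
    # rejection sampling jams near phi ~ 0.55; use a jittered lattice
    place_lattice_jitter(p$n_init, p$L, p$r)
  } else {
    place_non_overlapping(p$n_init, p$L, p$r, p$max_place_attempts)
  }
  hu <- matrix(
    as.integer(stats::runif(p$n_init * p$n_HU) < 0.5),
    nrow = p$n_init, ncol = p$n_HU, byrow = TRUE
  )
  cell_state(pos, hu)
}

#' @export
print.cell_state <- function(x, ...) {
  n <- nrow(x$pos)
  h <- if (n > 0) mean(cell_healths(x)) else NA_real_
  cat(sprintf(
    "cell_state: t = %g min, %d mitochondria, %d fusion bonds, mean health %.3f\n",
    x$time, n, nrow(x$bonds), h))
  invisible(x)
}

#' Per-mitochondrion healths of a cell state
#'
#' @param state a `cell_state`.
#' @return Numeric vector of health fractions, one per mitochondrion.
#' @export
cell_healths <- function(state) {
  if (nrow(state$hu) == 0) return(numeric(0))
  rowMeans(state$hu)
}

# event kind labels matching the compiled core's codes
event_kinds <- function() {
  c("damage", "fusion", "fission", "autophagy", "replication",
    "replication_blocked")
}

# raw core event columns -> tidy event log rows
tidy_events <- function(df) {
  kind <- event_kinds()[df$kind]
  motility <- rep(NA_character_, nrow(df))
  is_fus <- df$kind == 2L
  motility[is_fus] <- motility_levels()[df$d1[is_fus] + 1L]
  out <- data.frame(
    time = df$time,
    kind = kind,
    id1 = df$id1,
    id2 = df$id2,
    motility = motility,
    n_units = ifelse(df$kind == 1L, df$d1, NA_real_),
    health = ifelse(df$kind %in% c(4L, 5L, 6L), df$d1, NA_real_),
    h_a = ifelse(df$kind == 3L, df$d1, NA_real_),
    h_b = ifelse(df$kind == 3L, df$d2, NA_real_),
    h_a_post = ifelse(df$kind == 3L, df$d3, NA_real_),
    h_b_post = ifelse(df$kind == 3L, df$d4, NA_real_),
    stringsAsFactors = FALSE
  )
  out
}

empty_events <- function() {
  tidy_events(data.frame(time = numeric(0), kind = integer(0),
                         id1 = integer(0), id2 = integer(0),
                         d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
                         d4 = numeric(0)))
}

#' Write an event log as keyed text
#'
#' One record per line in a self-describing `key=value` format.
#'
#' @param events an event-log data frame (as found in a trajectory's
#'   `events` element).
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  fmt_num <- function(v) {
    ifelse(is.na(v), "NA", trimws(format(v, digits = 10, trim = TRUE)))
  }
  lines <- sprintf(
    "time=%s kind=%s id1=%s id2=%s motility=%s detail=%s",
    fmt_num(events$time), events$kind,
    ifelse(is.na(events$id1), "NA", events$id1),
    ifelse(is.na(events$id2), "NA", events$id2),
    ifelse(is.na(events$motility), "NA", events$motility),
    ifelse(!is.na(events$health), fmt_num(events$health),
           ifelse(!is.na(events$h_a),
                  paste0(fmt_num(events$h_a), ",", fmt_num(events$h_b), ",",
                         fmt_num(events$h_a_post), ",",
                         fmt_num(events$h_b_post)),
                  fmt_num(events$n_units)))
  )
  writeLines(lines, path)
  invisible(path)
}
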