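# helpers to build small, fully specified cell states for unit tests

# a state with mitochondria at given positions; hu rows default to
# all-healthy; motion/theta/bonds optional
make_state <- function(pos, hu = NULL, n_HU = 10, motion = NULL,
                       theta = NULL, bonds = NULL) {
  pos <- matrix(pos, ncol = 2)
  n <- nrow(pos)
  if (is.null(hu)) hu <- matrix(1L, n, n_HU)
  cell_state(pos, hu, motion = motion, theta = theta, bonds = bonds)
}

# hu vector with k healthy units out of n
hu_frac <- function(k, n = 10) c(rep(1L, k), rep(0L, n - k))

# parameters with every process switched off (geometry defaults kept);
# named arguments override the zeros
null_params <- function(...) {
  zeros <- list(k_damage = 0, k_fus = 0, k_fis = 0, k_aut = 0, k_rep = 0,
                k_on = 0)
  validate_params(utils::modifyList(zeros, list(...)))
}

# brute-force R contact scan: all pairs with center distance <= 2r + tol
brute_contacts <- function(state, r, tol) {
  n <- nrow(state$pos)
  out <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d <- sqrt(sum((state$pos[i, ] - state$pos[j, ])^2))
        if (d <= 2 * r + tol) {
          out <- rbind(out, c(state$id[i], state$id[j]))
        }
      }
    }
  }
  out
}

# exact post-exchange distribution of the number of healthy units in `a`,
# by enumeration over all position choices in both vectors
exchange_pmf <- function(a, b, n_ex) {
  N <- length(a)
  sets <- utils::combn(N, n_ex)
  if (n_ex == 0) sets <- matrix(integer(0), nrow = 0, ncol = 1)
  ga <- apply(sets, 2, function(s) sum(a[s]))   # healthy units leaving a
  gb <- apply(sets, 2, function(s) sum(b[s]))   # healthy units entering a
  if (n_ex == 0) { ga <- 0; gb <- 0 }
  vals <- outer(gb, ga, function(x, y) sum(a) - y + x)
  tab <- table(vals) / length(vals)
  pmf <- stats::setNames(as.numeric(tab), names(tab))
  pmf
}
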