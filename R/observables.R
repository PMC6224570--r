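#' Polaritonic and uncoupled-state populations versus time
#'
#' The polaritonic population of state Gamma is the fraction of trajectories
#' whose active state is Gamma; the uncoupled population of basis state i is
#' the ensemble mean of `|C_i^Gamma(active)|^2`, the composition of the
#' active state (the accounting matching the photon-loss weights). The
#' amplitude-based polaritonic populations (mean `|A_Gamma|^2`) are emitted
#' alongside for comparison.
#'
#' @param ensemble a `polhop_ensemble`.
#' @return data frame: `t_fs`, `pol_1..n` (active fractions, sorted-energy
#'   order: for the shipped parameter ranges 1 = |S0,0>-like, 2 = |->,
#'   3 = |+>, 4 = |S1,1>-like), `unc_*` (uncoupled-state means), `amp_1..n`.
#' @export
population_series <- function(ensemble) {
  trajs <- ensemble$trajectories
  if (length(trajs) == 0) stop("empty ensemble")
  nt <- length(ensemble$t_au)
  n <- ensemble$n_states
  polm <- matrix(0, nt, n)
  uncm <- matrix(0, nt, n)
  ampm <- matrix(0, nt, n)
  idx_t <- seq_len(nt)
  for (tr in trajs) {
    ii <- pmin(idx_t, length(tr$t))
    a <- tr$active[ii]
    polm[cbind(idx_t, a)] <- polm[cbind(idx_t, a)] + 1
    uncm <- uncm + tr$c_active_sq[ii, , drop = FALSE]
    ampm <- ampm + tr$amp_pop[ii, , drop = FALSE]
  }
  ntraj <- length(trajs)
  df <- data.frame(t_fs = au_to_fs(ensemble$t_au), polm / ntraj,
                   uncm / ntraj, ampm / ntraj)
  ucn <- if (n == 4L) c("unc_S00", "unc_S10", "unc_S01", "unc_S11")
         else c("unc_S0", "unc_S1")
  names(df) <- c("t_fs", paste0("pol_", seq_len(n)), ucn,
                 paste0("amp_", seq_len(n)))
  df
}

#' Electronic ground-state population versus time
#'
#' Ensemble mean of the electronic-S0 weight of the active state
#' (`|C_{S0,0}|^2 + |C_{S0,1}|^2` for the 4-state system). In the
#' weak-coupling limit this stays near zero until trajectories reach the
#' electronic conical intersection, whereas strong coupling transfers
#' ground-state character from the start of the dynamics.
#'
#' @param ensemble a `polhop_ensemble`.
#' @return data frame `t_fs`, `pop_ground_elec`.
#' @export
electronic_ground_population <- function(ensemble) {
  ps <- population_series(ensemble)
  pg <- if (ensemble$n_states == 4L) ps$unc_S00 + ps$unc_S01 else ps$unc_S0
  data.frame(t_fs = ps$t_fs, pop_ground_elec = pg)
}

#' First time a population series crosses a threshold
#'
#' @param t time vector.
#' @param pop population vector.
#' @param threshold crossing level (default 0.05).
#' @return first time with `pop >= threshold`, or `Inf`.
#' @export
onset_time <- function(t, pop, threshold = 0.05) {
  i <- which(pop >= threshold)
  if (length(i) == 0) Inf else t[i[1]]
}

#' Photoisomerization quantum yield
#'
#' Fraction of trajectories ending in the cis region (torsion classified at
#' the final snapshot), counted over the whole ensemble but requiring the
#' trajectory to have reached the lowest polaritonic (ground-like) state;
#' trajectories still electronically excited at the end of the run are
#' counted as non-reactive and reported separately.
#'
#' @param ensemble a `polhop_ensemble` run on a torsional model.
#' @param model the model (for the isomer classification).
#' @return list with `yield`, binomial `stderr`, and the counts
#'   `n_cis`, `n_trans`, `n_still_excited`, `n_total`.
#' @export
quantum_yield <- function(ensemble, model) {
  trajs <- ensemble$trajectories
  n_total <- length(trajs)
  n_cis <- n_ground <- 0
  for (tr in trajs) {
    last <- length(tr$t)
    on_ground <- tr$active[last] == 1L
    if (on_ground) {
      n_ground <- n_ground + 1
      th <- tr$q[last, 1]
      g <- geometry(th, tr$inertia[1], angular = tr$angular[1],
                    degrees = FALSE)
      if (classify_isomer(g) == "cis") n_cis <- n_cis + 1
    }
  }
  yield <- n_cis / n_total
  list(yield = yield,
       stderr = sqrt(max(yield * (1 - yield), 1e-12) / n_total),
       n_cis = n_cis, n_trans = n_ground - n_cis,
       n_still_excited = n_total - n_ground, n_total = n_total)
}

#' Averaged oscillation coordinate
#'
#' Trajectories are flagged "oscillating" when they undergo at least
#' `min_hops` accepted hops between the lower and upper polaritons (sorted
#' states 2 and 3); the per-time mean of the internal coordinates over the
#' flagged subset traces the oscillation coordinate (a hybrid of the
#' torsion and the bend for the 2-D surrogate).
#'
#' @param ensemble a `polhop_ensemble`.
#' @param min_hops minimum number of accepted |-> <-> |+> hops (default 2).
#' @return data frame `t_fs`, per-coordinate means (degrees for angular
#'   coordinates), and attribute `n_osc`. A zero-row frame (with a warning)
#'   if no trajectory qualifies.
#' @export
oscillation_coordinate <- function(ensemble, min_hops = 2) {
  trajs <- ensemble$trajectories
  osc <- vapply(trajs, function(tr) {
    h <- tr$hops
    sum(h$accepted == 1L &
          ((h$from == 2L & h$to == 3L) | (h$from == 3L & h$to == 2L))) >=
      min_hops
  }, logical(1))
  nt <- length(ensemble$t_au)
  nc <- ncol(trajs[[1]]$q)
  ang <- trajs[[1]]$angular
  cn <- if (trajs[[1]]$model_name == "azo2d")
    c("theta_deg", "alpha_deg") else paste0("q", seq_len(nc))
  if (!any(osc)) {
    warning("no oscillating trajectories under the given criterion")
    out <- data.frame(matrix(numeric(0), 0, nc + 1))
    names(out) <- c("t_fs", cn)
    attr(out, "n_osc") <- 0L
    return(out)
  }
  acc <- matrix(0, nt, nc)
  idx_t <- seq_len(nt)
  for (tr in trajs[osc]) {
    ii <- pmin(idx_t, length(tr$t))
    acc <- acc + tr$q[ii, , drop = FALSE]
  }
  acc <- acc / sum(osc)
  acc[, ang] <- rad_to_deg(acc[, ang])
  out <- data.frame(au_to_fs(ensemble$t_au), acc)
  names(out) <- c("t_fs", cn)
  attr(out, "n_osc") <- sum(osc)
  out
}

#' Count sign reversals of the time derivative of a series
#'
#' Used to quantify sustained oscillation of the averaged coordinate.
#'
#' @param t time vector; `x` series; `t_max` restrict to `t <= t_max`.
#' @param smooth width (samples) of a running-mean presmoothing.
#' @return number of sign changes of `dx/dt`.
#' @export
count_turning_points <- function(t, x, t_max = Inf, smooth = 5) {
  keep <- t <= t_max
  x <- x[keep]
  if (smooth > 1 && length(x) > smooth)
    x <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
  dx <- diff(x)
  dx <- dx[!is.na(dx) & dx != 0]
  sum(diff(sign(dx)) != 0)
}
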