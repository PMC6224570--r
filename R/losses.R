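#' Cavity photon-loss settings
#'
#' Photon escape from the cavity at rate `kappa = 1/tau_c` is applied a
#' posteriori to stored trajectories as a Monte Carlo process: at each step
#' the loss probability is `p_cav = (dt/tau_c) |C_{S0,1}^Gamma(t)|^2`, the
#' population of the one-photon ground-electronic product state in the
#' current polaritonic state Gamma. On a loss event the wavefunction
#' collapses onto |S0,0> and the trajectory is stopped. The (very unlikely)
#' back-transfer from |S0,1> to |S1,0> after a collapse is not modeled.
#'
#' @param tau_c_fs photon lifetime, fs (> 0).
#' @param replicas number of stochastic replicas per trajectory (default 5,
#'   turning 300 trajectories into 1500 loss realizations).
#' @param seed RNG seed for the loss draws (independent of the dynamics
#'   streams).
#' @return an object of class `loss_settings` (also carries
#'   `kappa = 1/tau_c`).
#' @export
loss_settings <- function(tau_c_fs, replicas = 5, seed = 1) {
  if (tau_c_fs <= 0) stop("photon lifetime must be positive")
  if (replicas < 1) stop("at least one replica required")
  structure(list(tau_c_fs = tau_c_fs, tau_c_au = fs_to_au(tau_c_fs),
                 kappa_au = 1 / fs_to_au(tau_c_fs),
                 replicas = as.integer(replicas), seed = as.integer(seed)),
            class = "loss_settings")
}

#' Resample one trajectory under cavity losses
#'
#' Draws one uniform number per stored step and records the first step where
#' it falls below `p_cav(t)`; the replica is then collapsed to |S0,0> and
#' stopped.
#'
#' @param traj a `polhop_trajectory` carrying the per-step
#'   `|C_{S0,1}^Gamma|^2` record.
#' @param settings a [loss_settings()].
#' @param u optional vector of uniform draws (one per step after the
#'   initial snapshot); supplied externally for common-random-number
#'   comparisons across lifetimes. Drawn from R's RNG when omitted.
#' @return list with `collapsed` (logical), `step` (index of the collapse
#'   snapshot or NA), and `t_au` (collapse time or NA).
#' @export
loss_resample <- function(traj, settings, u = NULL) {
  ps <- traj$c_s01_sq
  if (is.null(ps)) stop("trajectory record lacks the |C_S0,1|^2 series")
  nstep <- length(ps) - 1
  if (is.null(u)) u <- stats::runif(nstep)
  if (length(u) < nstep) stop("need one uniform draw per step")
  p_cav <- (traj$dt_au / settings$tau_c_au) * ps[-1]
  hit <- which(u[seq_len(nstep)] < p_cav)
  if (length(hit) == 0)
    return(list(collapsed = FALSE, step = NA_integer_, t_au = NA_real_))
  k <- hit[1]
  list(collapsed = TRUE, step = k + 1L, t_au = traj$t[k + 1L])
}

#' Apply the photon-loss model to a whole ensemble
#'
#' Each trajectory is replicated `replicas` times with independent,
#' seed-derived draws. A collapsed replica contributes to the |S0,0>
#' population for all later times (trajectory stopped); surviving replicas
#' keep their lossless record. Because the Fig.-style uncoupled-state curves
#' can be averaged either over all replicas or over survivors only, both
#' accountings are emitted.
#'
#' @param ensemble a `polhop_ensemble` (4-state).
#' @param settings a [loss_settings()].
#' @return an object of class `polhop_loss_ensemble`: per-time populations
#'   table (`populations`), collapse times, and settings. The table carries
#'   `t_fs`, `pop_ground` (collapsed + |S0,0>-dominant active survivors),
#'   polaritonic populations `pop_minus`, `pop_plus`, `pop_s11_like`,
#'   uncoupled-state means over all replicas (`pop_S10`, `pop_S01`, ...)
#'   and over survivors (`*_surv`), and `n_surviving`.
#' @export
ensemble_losses <- function(ensemble, settings) {
  if (ensemble$n_states != 4L)
    stop("loss post-processing needs the 4-state polaritonic record")
  trajs <- ensemble$trajectories
  nt <- length(ensemble$t_au)
  R <- settings$replicas
  # replica bookkeeping
  collapse_step <- matrix(NA_integer_, length(trajs), R)
  for (k in seq_along(trajs)) {
    for (r in seq_len(R)) {
      set.seed((settings$seed * 1000003 + k * 7919 + r * 104729) %%
                 2147483562 + 1)
      out <- loss_resample(trajs[[k]], settings)
      if (out$collapsed) collapse_step[k, r] <- out$step
    }
  }
  nrep <- length(trajs) * R
  pop_ground <- pop_minus <- pop_plus <- pop_s11 <- numeric(nt)
  unc_all <- matrix(0, nt, 4)
  unc_surv <- matrix(0, nt, 4)
  n_surv <- numeric(nt)
  idx_t <- seq_len(nt)
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    ii <- pmin(idx_t, length(tr$t))  # failed trajectories: hold last snapshot
    cc <- tr$c_active_sq[ii, , drop = FALSE]
    a <- tr$active[ii]
    dom_g <- cc[, 1] > 0.5           # |S0,0>-dominant active state
    m_ind <- !dom_g & a == 2L
    p_ind <- !dom_g & a == 3L
    s_ind <- !dom_g & a == 4L
    for (r in seq_len(R)) {
      cs <- collapse_step[k, r]
      alive <- if (is.na(cs)) rep(TRUE, nt) else idx_t < cs
      dead <- !alive
      pop_ground <- pop_ground + dead + alive * dom_g
      pop_minus <- pop_minus + alive * m_ind
      pop_plus <- pop_plus + alive * p_ind
      pop_s11 <- pop_s11 + alive * s_ind
      unc_all <- unc_all + alive * cc
      unc_all[, 1] <- unc_all[, 1] + dead
      unc_surv <- unc_surv + alive * cc
      n_surv <- n_surv + alive
    }
  }
  pop_ground <- pop_ground / nrep; pop_minus <- pop_minus / nrep
  pop_plus <- pop_plus / nrep; pop_s11 <- pop_s11 / nrep
  unc_all <- unc_all / nrep
  unc_surv <- unc_surv / ifelse(n_surv > 0, n_surv, NA_real_)
  tab <- data.frame(t_fs = au_to_fs(ensemble$t_au),
                    pop_ground = pop_ground, pop_minus = pop_minus,
                    pop_plus = pop_plus, pop_s11_like = pop_s11,
                    pop_S00 = unc_all[, 1], pop_S10 = unc_all[, 2],
                    pop_S01 = unc_all[, 3], pop_S11 = unc_all[, 4],
                    pop_S00_surv = unc_surv[, 1], pop_S10_surv = unc_surv[, 2],
                    pop_S01_surv = unc_surv[, 3], pop_S11_surv = unc_surv[, 4],
                    n_surviving = n_surv)
  structure(list(populations = tab,
                 collapse_step = collapse_step,
                 collapse_t_fs = au_to_fs(ensemble$t_au[
                   ifelse(is.na(collapse_step), NA_integer_, collapse_step)]),
                 settings = settings, n_replicas = nrep),
            class = "polhop_loss_ensemble")
}

#' @export
print.polhop_loss_ensemble <- function(x, ...) {
  cat(sprintf("<polhop_loss_ensemble> tau_c = %g fs, %d replicas, %d collapsed\n",
              x$settings$tau_c_fs, x$n_replicas,
              sum(!is.na(x$collapse_step))))
  invisible(x)
}
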