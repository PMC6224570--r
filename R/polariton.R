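#' Single-mode cavity description
#'
#' The quantized field mode contributes `omega_ph (b'b + 1/2)` to the total
#' Hamiltonian and couples to the molecular transition dipole as
#' `g mu(Q) . lambda (b' + b)` (dipolar coupling, counter-rotating terms
#' retained: extended Jaynes-Cummings). The photon basis is truncated at
#' occupation 1, giving the four uncoupled product states
#' |S0,0>, |S1,0>, |S0,1>, |S1,1> (this fixed order indexes all coefficient
#' matrices). `n_photon = 1` truncates at occupation 0, which yields the
#' photon-free two-state reference system used for weak-coupling baselines.
#'
#' @param energy_ev photon energy, eV (> 0).
#' @param g coupling constant, au (>= 0).
#' @param polarization field polarization 3-vector; must have unit norm.
#' @param n_photon number of photon occupation states kept (1 or 2).
#' @return an object of class `cavity_mode`.
#' @examples
#' cavity_mode(1.3, 0.010)           # the reference strong-coupling cavity
#' cavity_mode(1.3, 0, n_photon = 1) # photon-free two-state reference
#' @export
cavity_mode <- function(energy_ev, g, polarization = c(0, 0, 1),
                        n_photon = 2) {
  if (!is.finite(energy_ev) || energy_ev <= 0)
    stop("photon energy must be positive")
  if (!is.finite(g) || g < 0) stop("coupling constant g must be >= 0")
  nrm <- sqrt(sum(polarization^2))
  if (abs(nrm - 1) > 1e-6)
    stop("polarization must be a unit vector (|lambda| = 1)")
  if (!n_photon %in% c(1L, 2L)) stop("n_photon must be 1 or 2")
  structure(list(omega = ev_to_hartree(energy_ev), g = g,
                 lam = polarization / nrm, n_photon = as.integer(n_photon),
                 n_states = 2L * as.integer(n_photon)),
            class = "cavity_mode")
}

#' @export
print.cavity_mode <- function(x, ...) {
  cat(sprintf("<cavity_mode> omega = %.4f eV, g = %.4f au, lambda = (%g, %g, %g), %d photon state(s)\n",
              hartree_to_ev(x$omega), x$g, x$lam[1], x$lam[2], x$lam[3],
              x$n_photon))
  invisible(x)
}

#' Build the total light-molecule Hamiltonian
#'
#' In the uncoupled basis |S0,0>, |S1,0>, |S0,1>, |S1,1> the matrix has
#' diagonal (E0 + w/2, E1 + w/2, E0 + 3w/2, E1 + 3w/2) and the coupling
#' element V = g (mu . lambda) on the rotating pair (|S1,0>, |S0,1>) and the
#' counter-rotating pair (|S0,0>, |S1,1>). All other entries vanish: the
#' interaction only connects states differing by one photon through the
#' transition dipole.
#'
#' @param elec an `electronic_structure` from [evaluate()].
#' @param cavity a [cavity_mode()].
#' @return a symmetric `n_states x n_states` matrix, hartree.
#' @export
build_hamiltonian <- function(elec, cavity) {
  w <- cavity$omega
  if (cavity$n_states == 2L)
    return(diag(c(elec$E0 + w / 2, elec$E1 + w / 2)))
  V <- cavity$g * sum(elec$mu_vec * cavity$lam)
  H <- diag(c(elec$E0 + w / 2, elec$E1 + w / 2,
              elec$E0 + 1.5 * w, elec$E1 + 1.5 * w))
  H[2, 3] <- H[3, 2] <- V
  H[1, 4] <- H[4, 1] <- V
  H
}

#' Diagonalize a polaritonic Hamiltonian
#'
#' Exact eigensolution with energies sorted ascending. When a `previous`
#' solution is supplied, each eigenvector column is sign-fixed so that its
#' largest-magnitude overlap with the previous solution is positive
#' (continuity along a trajectory); otherwise the largest-magnitude entry of
#' each column is made positive. At exact degeneracies the order is fixed by
#' the dominant uncoupled character (photon number, then electronic index).
#'
#' @param H symmetric Hamiltonian matrix (2x2 or 4x4).
#' @param previous optional previous `polariton_solution` for sign
#'   continuity.
#' @param elec_ov optional 2x2 electronic overlap between the geometries of
#'   `previous` and `H` (identity if omitted).
#' @return an object of class `polariton_solution` with fields `energies`,
#'   coefficient matrix `C` (columns = polaritonic states over the uncoupled
#'   basis), and the coupling element `V`.
#' @export
solve_polaritons <- function(H, previous = NULL, elec_ov = NULL) {
  n <- nrow(H)
  stopifnot(ncol(H) == n, n %in% c(2L, 4L))
  if (max(abs(H - t(H))) > 1e-12) stop("H must be symmetric")
  shat <- if (is.null(elec_ov)) NULL else photon_block_overlap(elec_ov, n)
  cprev <- if (is.null(previous)) NULL else previous$C
  s <- .solve_pol_cpp(H, cprev, shat)
  structure(list(energies = s$energies, C = s$C,
                 V = if (n == 4L) H[2, 3] else 0,
                 n = n, overlap = if (is.null(previous)) NULL else s$overlap),
            class = "polariton_solution")
}

# lift a 2x2 electronic overlap to the uncoupled light-matter basis:
# entries s_el[e_i, e_j] * delta(photon_i, photon_j)
photon_block_overlap <- function(elec_ov, n = 4L) {
  if (n == 2L) return(elec_ov)
  S <- matrix(0, 4, 4)
  S[1:2, 1:2] <- elec_ov
  S[3:4, 3:4] <- elec_ov
  S
}

#' Gradient of a polaritonic surface
#'
#' Hellmann-Feynman contract: `grad E_G = sum_ij C_iG C_jG grad H_ij`,
#' combining the electronic adiabatic gradients on the diagonal and
#' `g lambda . grad mu` on the two coupling entries.
#'
#' @param elec an `electronic_structure`.
#' @param cavity a `cavity_mode`.
#' @param sol the `polariton_solution` at the same geometry.
#' @param state polaritonic state index (1-based, sorted order).
#' @return gradient vector, hartree per coordinate unit.
#' @export
polaritonic_gradient <- function(elec, cavity, sol, state) {
  n <- sol$n
  stopifnot(state >= 1, state <= n)
  gaps <- abs(sol$energies - sol$energies[state])
  if (any(gaps[-state] < 1e-10))
    stop(errorCondition("degenerate polaritonic eigenvalue at evaluation point",
                        class = "polhop_degeneracy"))
  C <- sol$C[, state]
  nc <- length(elec$grad0)
  dV <- cavity$g * as.numeric(cavity$lam %*% elec$grad_mu_vec)
  g <- C[1]^2 * elec$grad0 + C[2]^2 * elec$grad1
  if (n == 4L) {
    g <- g + C[3]^2 * elec$grad0 + C[4]^2 * elec$grad1 +
      2 * (C[2] * C[3] + C[1] * C[4]) * dV
  }
  g
}

#' Overlap between polaritonic solutions at neighboring geometries
#'
#' `S[G, G'] = sum_ij C_iG(a) C_jG'(b) s_el[e_i, e_j] delta(n_i, n_j)`:
#' electronic overlaps, blocked by photon number, rotated into the two
#' polaritonic bases.
#'
#' @param sol_a,sol_b `polariton_solution`s at the two geometries.
#' @param elec_ov 2x2 electronic overlap matrix between the geometries.
#' @return `n x n` overlap matrix, rows indexing states of `sol_a`.
#' @export
polaritonic_overlap <- function(sol_a, sol_b, elec_ov) {
  S <- photon_block_overlap(elec_ov, sol_a$n)
  t(sol_a$C) %*% S %*% sol_b$C
}

#' Scan polaritonic potential energy surfaces on a coordinate grid
#'
#' Evaluates the four polaritonic energies on a (torsion, bend) grid,
#' reports the |-> / |+> gap (the two states with dominant rotating-block
#' character) and the minimum-gap point, and, for a z-polarized field on the
#' 2-D surrogate, locates the polaritonic conical intersection: the planar
#' point where the uncoupled crossing condition E1 - E0 = omega holds while
#' mu . lambda = 0, so the polaritons become exactly degenerate.
#'
#' @param model a `polhop_model`.
#' @param cavity a `cavity_mode` (4-state).
#' @param theta_deg,alpha_deg grid axes, degrees.
#' @param out_csv optional path; the scan table is written as CSV with a
#'   unit header.
#' @return list with the scan `table` (energies and gap in eV), the
#'   `min_gap` row, and `pci` (polaritonic conical intersection location or
#'   NULL).
#' @export
scan_ppes <- function(model, cavity, theta_deg, alpha_deg = NULL,
                      out_csv = NULL) {
  if (length(theta_deg) == 0 || (!is.null(alpha_deg) && length(alpha_deg) == 0))
    stop("empty scan grid")
  if (cavity$n_states != 4L) stop("scan requires the 4-state cavity")
  grid <- if (is.null(alpha_deg)) {
    matrix(theta_deg, ncol = 1)
  } else {
    as.matrix(expand.grid(theta = theta_deg, alpha = alpha_deg))
  }
  coords <- grid
  coords[, model$angular] <- deg_to_rad(coords[, model$angular])
  s <- .scan_cpp(model$id, model$params, cavity$omega, cavity$g, cavity$lam,
                 coords)
  tab <- data.frame(grid,
                    E1_ev = hartree_to_ev(s$energies[, 1]),
                    E2_ev = hartree_to_ev(s$energies[, 2]),
                    E3_ev = hartree_to_ev(s$energies[, 3]),
                    E4_ev = hartree_to_ev(s$energies[, 4]),
                    gap_pm_ev = hartree_to_ev(s$gap_pm),
                    elec_gap_ev = hartree_to_ev(s$elec_gap),
                    mu_dot_lam = s$mu_dot_lam,
                    c_s01_sq_1 = s$c_s01_sq[, 1],
                    c_s01_sq_2 = s$c_s01_sq[, 2],
                    c_s01_sq_3 = s$c_s01_sq[, 3],
                    c_s01_sq_4 = s$c_s01_sq[, 4])
  imin <- which.min(tab$gap_pm_ev)
  pci <- if (model$name == "azo2d") {
    tryCatch(locate_pci(model, cavity), error = function(e) NULL)
  } else NULL
  if (!is.null(out_csv)) {
    write_table_csv(tab, out_csv,
                    comment = "PPES scan: angles deg, energies eV")
  }
  list(table = tab, min_gap = tab[imin, ], pci = pci)
}

#' Locate the polaritonic conical intersection of the 2-D surrogate
#'
#' For a field polarized out of plane the coupling g (mu . lambda) vanishes
#' at planar geometries, so the |-> / |+> splitting collapses wherever the
#' uncoupled surfaces also cross (E1 - E0 = omega): a true polaritonic
#' conical intersection. This solves E1 - E0 = omega along the planar line
#' theta = 180 deg.
#'
#' @param model the `azo2d` surrogate.
#' @param cavity a 4-state `cavity_mode`.
#' @param theta_planar planar torsion, degrees (0 or 180).
#' @param alpha_range bend search interval, degrees.
#' @return list with `theta_deg`, `alpha_deg`, and the polaritonic `gap_ev`
#'   at the located point.
#' @export
locate_pci <- function(model, cavity, theta_planar = 180,
                       alpha_range = c(60, 180)) {
  th <- deg_to_rad(theta_planar)
  f <- function(al) {
    e <- evaluate(model, c(th, deg_to_rad(al)))
    (e$E1 - e$E0) - cavity$omega
  }
  lo <- alpha_range[1]; hi <- alpha_range[2]
  grid <- seq(lo, hi, length.out = 241)
  vals <- vapply(grid, f, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (length(sgn) == 0)
    stop("no uncoupled crossing E1 - E0 = omega on the planar line")
  r <- stats::uniroot(f, c(grid[sgn[1]], grid[sgn[1] + 1]), tol = 1e-12)
  al <- r$root
  e <- evaluate(model, c(th, deg_to_rad(al)))
  H <- build_hamiltonian(e, cavity)
  sol <- solve_polaritons(H)
  wt <- sol$C[2, ]^2 + sol$C[3, ]^2
  pair <- order(wt, decreasing = TRUE)[1:2]
  list(theta_deg = theta_planar, alpha_deg = al,
       gap_ev = hartree_to_ev(abs(diff(sol$energies[pair]))),
       mu_dot_lam = sum(e$mu_vec * cavity$lam))
}
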