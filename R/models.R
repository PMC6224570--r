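#' Analytic electronic-structure models
#'
#' A model supplies, at any geometry, the two adiabatic electronic energies
#' and gradients, the transition-dipole vector and its gradient, and the
#' diabatic-to-adiabatic mixing angle. Both shipped models derive their
#' adiabatic quantities from a 2x2 diabatic potential matrix
#' (H11, H22, H12) by exact diagonalization.
#'
#' `azo2d_model()` is the two-dimensional azobenzene-like photoswitch
#' surrogate in the torsion/bend plane:
#' \deqn{H_{11} = A_0 \sin^2\theta + \tfrac{c_{cis}}{2}(1+\cos\theta)
#'   + \tfrac{k_0}{2}(\alpha-\alpha_0)^2}
#' \deqn{H_{22} = E_v - A_1 \sin^2\theta + \tfrac{k_1}{2}(\alpha-\alpha_1)^2}
#' \deqn{H_{12} = \gamma_{12} \cos\theta, \qquad
#'   \mu = (0, 0, \mu_0 \sin\theta)}
#' It has a ground-state torsional double well (trans at 180 deg, cis at 0),
#' an excited state descending toward a twisted conical intersection on the
#' theta = 90 line, a bend coordinate modulating the gap, and an out-of-plane
#' transition dipole that vanishes exactly at planar geometries
#' (theta in \{0, 180\} deg).
#'
#' `curve1d_model()` is a one-dimensional avoided-crossing model
#' (H11 = A tanh(Bx) = -H22, H12 = C exp(-D x^2), constant dipole) used for
#' Landau-Zener and exact-wavepacket validation.
#'
#' @param A0,c_cis,E_v,A1 torsional energy scales, eV.
#' @param alpha0,alpha1 equilibrium bend angles of the two diabats, degrees.
#' @param k0,k1 bend force constants, eV per squared radian.
#' @param gamma12 diabatic electronic coupling amplitude, eV.
#' @param mu0 transition-dipole amplitude, au.
#' @param inertia effective inertias (torsion, bend), atomic units. Defaults
#'   chosen once so the excited-state torsional descent takes roughly 100 fs
#'   and the bending period is 30 fs.
#' @param A,B,C,D curve1d diabatic parameters, atomic units.
#' @param mass curve1d particle mass, atomic units.
#' @return an object of class `polhop_model`.
#' @examples
#' m <- azo2d_model()
#' evaluate(m, geometry(c(170, 115), m$inertia))
#' @name electronic_models
NULL

new_model <- function(name, id, params, inertia, ncoord, angular, q_ref,
                      fun = NULL) {
  structure(list(name = name, id = id, params = params, inertia = inertia,
                 ncoord = ncoord, angular = angular, q_ref = q_ref,
                 fun = fun),
            class = "polhop_model")
}

#' @rdname electronic_models
#' @export
azo2d_model <- function(A0 = 1.6, c_cis = 0.6, E_v = 2.8, A1 = 1.4,
                        alpha0 = 115, alpha1 = 130, k0 = 8.73, k1 = 8.73,
                        gamma12 = 0.15, mu0 = 1.0,
                        inertia = c(1.5e5, 1.25e4)) {
  params <- c(ev_to_hartree(A0), ev_to_hartree(c_cis), ev_to_hartree(E_v),
              ev_to_hartree(A1), deg_to_rad(alpha0), deg_to_rad(alpha1),
              ev_to_hartree(k0), ev_to_hartree(k1), ev_to_hartree(gamma12),
              mu0)
  if (!all(is.finite(params))) stop("model parameters must be finite")
  new_model("azo2d", 1L, params, inertia, 2L, c(TRUE, TRUE),
            q_ref = c(pi, deg_to_rad(alpha0)))
}

#' @rdname electronic_models
#' @export
curve1d_model <- function(A = 0.01, B = 1.6, C = 0.005, D = 1.0, mu0 = 1.0,
                          mass = 2000) {
  params <- c(A, B, C, D, mu0)
  if (!all(is.finite(params))) stop("model parameters must be finite")
  new_model("curve1d", 2L, params, mass, 1L, FALSE, q_ref = -6)
}

#' Look up a shipped model by registered name
#'
#' @param name `"azo2d"` or `"curve1d"`.
#' @param ... parameter overrides passed to the constructor.
#' @export
polhop_model <- function(name, ...) {
  switch(name,
         azo2d = azo2d_model(...),
         curve1d = curve1d_model(...),
         stop("unknown model name: ", name))
}

#' Evaluate a model at a geometry
#'
#' Returns the electronic-structure data contract: adiabatic energies E0 <=
#' E1 (hartree), their gradients (hartree per radian or per bohr), the
#' transition-dipole vector and its gradient (au), and the
#' diabatic-to-adiabatic mixing angle (radians).
#'
#' @param model a `polhop_model`.
#' @param Q a `polhop_geometry` (or bare numeric vector in internal units).
#' @return an object of class `electronic_structure`.
#' @export
evaluate <- function(model, Q) {
  q <- if (inherits(Q, "polhop_geometry")) Q$coords else as.numeric(Q)
  if (length(q) != model$ncoord)
    stop("geometry has ", length(q), " coordinates; model needs ",
         model$ncoord)
  if (!all(is.finite(q))) stop("non-finite coordinate")
  out <- if (is.null(model$fun)) {
    .model_eval_cpp(model$id, model$params, q)
  } else {
    model$fun(q)
  }
  if (out$E1 < out$E0) stop("model violates adiabatic ordering E1 >= E0")
  structure(out, class = "electronic_structure")
}

#' Electronic wavefunction overlap between two geometries
#'
#' For two-state models diagonalized by a rotation of the diabatic basis,
#' the overlap matrix between the adiabatic states at geometries a and b is
#' the rotation by the mixing-angle difference:
#' `[[cos(dphi), -sin(dphi)], [sin(dphi), cos(dphi)]]` with
#' `dphi = phi(b) - phi(a)`; it is exactly orthogonal.
#'
#' @param model a `polhop_model`.
#' @param Q_a,Q_b geometries.
#' @return a 2x2 orthogonal matrix, rows indexing states at `Q_a`.
#' @export
electronic_overlap <- function(model, Q_a, Q_b) {
  ea <- evaluate(model, Q_a)
  eb <- evaluate(model, Q_b)
  d <- eb$mixing_angle - ea$mixing_angle
  matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
}

#' @export
print.polhop_model <- function(x, ...) {
  cat("<polhop_model>", x$name, "-", x$ncoord, "coordinate(s)\n")
  invisible(x)
}
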