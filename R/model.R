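#' Sclerostin gate
#'
#' Osteocytes secrete sclerostin, which inhibits Wnt/beta-catenin signaling.
#' When the local osteocyte population \code{S} falls below the critical
#' threshold \code{K_S}, sclerostin drops and osteogenic signaling is
#' released. The gate factor is
#' \deqn{s = (1 - S/K_S)\,H(1 - S/K_S) = \max(0, 1 - S/K_S),}
#' a dimensionless value in [0, 1]: 0 when the osteocyte network is intact
#' (\code{S >= K_S}), 1 under complete local apoptosis (\code{S = 0}).
#' The Heaviside convention is \code{H(0) = 0}; the choice is immaterial
#' because the prefactor vanishes there, but it is fixed for reproducibility.
#'
#' @param S osteocyte population (cells); vectorized.
#' @param K_S critical osteocyte population (cells), must be positive.
#' @return Gate factor(s) in [0, 1].
#' @examples
#' sclerostin_gate(180, 200)  # 0.1
#' sclerostin_gate(220, 200)  # 0, clamped
#' @export
sclerostin_gate <- function(S, K_S) {
  if (!is.numeric(K_S) || length(K_S) != 1L || !is.finite(K_S) || K_S <= 0)
    stop_validation("K_S must be a finite number > 0")
  pmax(0, 1 - S / K_S)
}

#' Power-law signaling term
#'
#' Evaluates \code{base^exponent} under the conventions of the power-law
#' (biochemical systems) formalism: \code{0^e = 0} for \code{e > 0} and
#' \code{0^0 = 1}, so that setting an effectiveness exponent to zero removes
#' a regulator from a term instead of annihilating the term. A zero base
#' with a negative exponent is a domain error -- negative exponents are only
#' admissible on the epsilon-guarded osteoblast base.
#'
#' @param base nonnegative scalar or vector.
#' @param exponent dimensionless effectiveness exponent(s).
#' @return \code{base^exponent}, vectorized with recycling.
#' @examples
#' powerlaw(5, 0)  # 1
#' powerlaw(0, 2)  # 0
#' @export
powerlaw <- function(base, exponent) {
  if (any(base < 0, na.rm = TRUE))
    stop_domain("power-law base must be >= 0")
  if (any(base == 0 & exponent < 0, na.rm = TRUE))
    stop_domain("zero base with negative exponent: use the epsilon-guarded base")
  base^exponent
}

# Compiled-down scalar RHS closure used by the integrators. Parameter lookup
# happens once, not per step. Power bases are evaluated on max(x, 0) so that
# fractional exponents stay real under tiny negative solver excursions; the
# state itself is never clipped. The OPG base is epsilon + max(B, 0) >= epsilon.
make_derivs <- function(params) {
  p <- unclass(as_remodeling_params(params))
  a1 <- p[["alpha1"]]; a2 <- p[["alpha2"]]; a3 <- p[["alpha3"]]; a4 <- p[["alpha4"]]
  b1 <- p[["beta1"]]; b2 <- p[["beta2"]]; b3 <- p[["beta3"]]; dl <- p[["delta"]]
  K <- p[["K_S"]]; k1 <- p[["k1"]]; k2 <- p[["k2"]]; eps <- p[["epsilon"]]
  g31 <- p[["g31"]]; g21 <- p[["g21"]]; g22 <- p[["g22"]]; g32 <- p[["g32"]]
  g41 <- p[["g41"]]; g42 <- p[["g42"]]; g43 <- p[["g43"]]; g44 <- p[["g44"]]
  f12 <- p[["f12"]]; f14 <- p[["f14"]]; f23 <- p[["f23"]]; f34 <- p[["f34"]]
  function(t, y) {
    S <- y[1L]; P <- y[2L]; B <- y[3L]; C <- y[4L]
    Sp <- if (S > 0) S else 0
    Pp <- if (P > 0) P else 0
    Bp <- if (B > 0) B else 0
    Cp <- if (C > 0) C else 0
    s <- 1 - S / K
    if (s < 0) s <- 0
    embed <- a1 * Bp^g31 * s              # shared by dS and dB
    differ <- b1 * Pp^f12 * Cp^f14        # shared by dP and dB
    dS <- embed
    dP <- a2 * Sp^g21 * s^g22 + a3 * Pp^g32 * s - differ - dl * P
    dB <- differ - b2 * Bp^f23 - embed
    dC <- a4 * Sp^g41 * Pp^g42 * (eps + Bp)^g43 * s^g44 - b3 * Cp^f34
    dz <- k2 * B - k1 * C
    c(dS, dP, dB, dC, dz)
  }
}

#' Right-hand side of the remodeling model
#'
#' Evaluates the derivative of the five-variable targeted remodeling system
#' at a given state. With \code{s = sclerostin_gate(S, K_S)} the equations
#' are
#' \deqn{dS/dt = \alpha_1 B^{g_{31}} s}
#' \deqn{dP/dt = \alpha_2 S^{g_{21}} s^{g_{22}} + \alpha_3 P^{g_{32}} s
#'              - \beta_1 P^{f_{12}} C^{f_{14}} - \delta P}
#' \deqn{dB/dt = \beta_1 P^{f_{12}} C^{f_{14}} - \beta_2 B^{f_{23}}
#'              - \alpha_1 B^{g_{31}} s}
#' \deqn{dC/dt = \alpha_4 S^{g_{41}} P^{g_{42}} (\epsilon + B)^{g_{43}}
#'               s^{g_{44}} - \beta_3 C^{f_{34}}}
#' \deqn{dz/dt = -k_1 C + k_2 B}
#' The osteoblast embedding term is shared verbatim between the osteocyte
#' and osteoblast equations, and the pre-osteoblast differentiation term
#' between the pre-osteoblast and osteoblast equations, so cells are
#' conserved across those transitions. There is no osteocyte death term:
#' over a single remodeling event, osteocyte apoptosis enters only through
#' the initial condition. Bone volume \code{z} does not feed back on the
#' cell subsystem, so cell trajectories are independent of \code{k1, k2}.
#'
#' @param t time (days); the autonomous system ignores it, kept for solver
#'   compatibility.
#' @param state named or positional numeric vector \code{(S, P, B, C, z)};
#'   all components must be finite and the cell populations nonnegative.
#' @param params a [remodeling_params()] object.
#' @return Named numeric vector of per-day rates
#'   \code{c(S = , P = , B = , C = , z = )}.
#' @examples
#' p <- remodeling_params()
#' remodeling_rhs(0, c(S = 180, P = 0, B = 0, C = 0, z = 100), p)
#' @export
remodeling_rhs <- function(t, state, params = remodeling_params()) {
  if (!is.numeric(state) || length(state) != 5L)
    stop_validation("state must be a numeric vector (S, P, B, C, z)")
  if (any(!is.finite(state)))
    stop_domain("invalid state: non-finite component(s) at t = %g", t)
  if (any(state[1:4] < 0))
    stop_domain("invalid state: negative cell population(s) at t = %g", t)
  f <- make_derivs(params)
  d <- f(t, unname(state))
  names(d) <- c("S", "P", "B", "C", "z")
  d
}

#' Residual of the remodeling-free equilibrium
#'
#' The state \code{(K_S, 0, 0, 0, z)} -- an intact osteocyte network and no
#' committed pre-osteoblasts, osteoblasts or osteoclasts -- is a steady
#' state of the model: the sclerostin gate is closed and every remaining
#' term carries a factor of a zero population. This function evaluates the
#' infinity norm of the right-hand side there; it is exactly zero in exact
#' arithmetic for every admissible parameter set with positive exponents on
#' the cell-population bases.
#'
#' @param params a [remodeling_params()] object.
#' @param z0 bone volume at which to evaluate (immaterial); default 100.
#' @return Max-norm of the derivative vector (per-day rates).
#' @examples
#' equilibrium_residual(remodeling_params())  # 0
#' @export
equilibrium_residual <- function(params = remodeling_params(), z0 = 100) {
  params <- as_remodeling_params(params)
  state <- c(S = params[["K_S"]], P = 0, B = 0, C = 0, z = z0)
  max(abs(remodeling_rhs(0, state, params)))
}
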