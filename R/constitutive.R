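#' Blood properties
#'
#' Container for the fluid properties entering the 1D momentum balance:
#' density \code{rho}, dynamic viscosity \code{mu} and the polynomial order
#' \code{zeta} of the assumed axial velocity profile. \code{zeta} enters the
#' friction term \eqn{f = -2(\zeta+2)\mu\pi U}; \code{zeta = 9} corresponds to
#' a profile considerably flatter than Poiseuille flow, appropriate for large
#' arteries.
#'
#' @param rho blood density (g cm^-3).
#' @param mu dynamic viscosity (g cm^-1 s^-1, i.e. poise).
#' @param zeta velocity-profile polynomial order (dimensionless, >= 2).
#' @return an object of class \code{blood_properties}.
#' @export
#' @examples
#' blood_properties()          # defaults: rho = 1.06, mu = 0.035, zeta = 9
blood_properties <- function(rho = 1.06, mu = 0.035, zeta = 9) {
  stopifnot(is.numeric(rho), is.numeric(mu), is.numeric(zeta))
  if (rho <= 0) stop("blood density rho must be positive")
  if (mu <= 0) stop("blood viscosity mu must be positive")
  if (zeta < 2) stop("velocity-profile order zeta must be >= 2")
  structure(list(rho = rho, mu = mu, zeta = zeta), class = "blood_properties")
}

#' Friction coefficient 2(zeta+2)*pi*mu of the 1D momentum equation
#' @param blood a \code{blood_properties} object.
#' @return coefficient multiplying U in the friction term (g cm^-1 s^-1).
#' @export
friction_coefficient <- function(blood) 2 * (blood$zeta + 2) * pi * blood$mu

#' Wall stiffness law
#'
#' Empirical relation linking the diastolic lumen radius to the wall stiffness
#' product E*h via the diastolic pulse wave velocity:
#' \deqn{c_d^2 = \frac{2}{3\rho}\frac{Eh}{r_d} = \frac{2}{3\rho}\left[k_1 e^{k_2 r_d} + k_3\right].}
#' Two canonical coefficient sets are shipped: \code{"systemic"}
#' (k1 = 3e6 g s^-2 cm^-1, k2 = -9 cm^-1, k3 = 33.7e4 g s^-2 cm^-1) and the
#' stiffer \code{"coronary"} set (20e6, -22.5, 86.5e4).
#'
#' @param kind \code{"systemic"} or \code{"coronary"}; selects default k's.
#' @param k1,k2,k3 stiffness coefficients, overriding the kind defaults.
#' @return an object of class \code{wall_law}.
#' @export
wall_law <- function(kind = c("systemic", "coronary"),
                     k1 = NULL, k2 = NULL, k3 = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    systemic = c(3e6, -9, 33.7e4),
    coronary = c(20e6, -22.5, 86.5e4))
  k1 <- if (is.null(k1)) def[1] else k1
  k2 <- if (is.null(k2)) def[2] else k2
  k3 <- if (is.null(k3)) def[3] else k3
  structure(list(kind = kind, k1 = k1, k2 = k2, k3 = k3), class = "wall_law")
}

#' Wall stiffness product E*h at a diastolic radius
#' @param r_d diastolic radius (cm).
#' @param law a \code{wall_law}.
#' @return E*h (g s^-2 = dyn cm^-1).
#' @export
wall_Eh <- function(r_d, law) {
  if (any(r_d <= 0)) stop("diastolic radius must be positive")
  Eh <- r_d * (law$k1 * exp(law$k2 * r_d) + law$k3)
  if (any(Eh <= 0)) stop("unphysical wall law: E*h <= 0 at r_d = ",
                         paste(r_d[Eh <= 0], collapse = ", "))
  Eh
}

#' Diastolic pulse wave speed from the wall-stiffness law
#'
#' @param r_d diastolic radius (cm); vectorised.
#' @param law a \code{wall_law}.
#' @param blood a \code{blood_properties}.
#' @return c_d (cm s^-1).
#' @export
#' @examples
#' wave_speed(1.0, wall_law("systemic"), blood_properties())  # ~460.6 cm/s
wave_speed <- function(r_d, law, blood) {
  if (any(r_d <= 0)) stop("diastolic radius must be positive")
  rad <- (2 / (3 * blood$rho)) * (law$k1 * exp(law$k2 * r_d) + law$k3)
  if (any(rad <= 0)) stop("unphysical wall law: nonpositive c_d^2")
  sqrt(rad)
}

#' Tube-law stiffness parameter beta = (4/3) sqrt(pi) E h
#' @param r_d diastolic radius (cm).
#' @param law a \code{wall_law}.
#' @return beta (g s^-2 cm^-1 when combined with areas in cm^2).
#' @export
tube_beta <- function(r_d, law) (4 / 3) * sqrt(pi) * wall_Eh(r_d, law)

#' Elastic tube law and its inverse
#'
#' Pressure-area relation of a thin-walled elastic vessel,
#' \deqn{P = P_{dia} + \frac{\beta}{A_d}(\sqrt{A} - \sqrt{A_d})},
#' referenced to the diastolic state (A_d, P_dia). \code{tube_law_area} is the
#' exact inverse for pressures above wall collapse.
#'
#' @param A cross-sectional area (cm^2); vectorised.
#' @param P pressure (dyn cm^-2); vectorised.
#' @param A_d diastolic area (cm^2).
#' @param beta wall stiffness parameter (see \code{\link{tube_beta}}).
#' @param P_dia diastolic reference pressure (dyn cm^-2).
#' @return pressure (dyn cm^-2) for \code{tube_law}; area (cm^2) for
#'   \code{tube_law_area}.
#' @export
tube_law <- function(A, A_d, beta, P_dia) {
  if (any(A <= 0)) stop("area must be positive in tube_law")
  P_dia + (beta / A_d) * (sqrt(A) - sqrt(A_d))
}

#' @rdname tube_law
#' @export
tube_law_area <- function(P, A_d, beta, P_dia) {
  s <- sqrt(A_d) + (P - P_dia) * A_d / beta
  if (any(s <= 0)) stop("tube_law_area: pressure below collapse limit")
  s^2
}

#' Local wave speed at area A under the tube law: c^2 = A (dP/dA) / rho
#' @inheritParams tube_law
#' @param rho blood density (g cm^-3).
#' @return c (cm s^-1).
#' @export
local_wave_speed <- function(A, A_d, beta, rho) {
  sqrt(beta * sqrt(A) / (2 * rho * A_d))
}
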