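#' Wall and blood constitutive parameters
#'
#' Container for the parameters of the viscoelastic tube law closing the 1D
#' system. The elastic part is
#' \deqn{P - P_0 - P_{ext} = \frac{2\rho c_0^2}{b}\left[(A/A_0)^{b/2} - 1\right]}
#' with stiffness exponent \eqn{b = 2\rho c_0^2 / (P_0 - P_{collapse})} and a
#' reference wave speed from the empirical diameter law
#' \eqn{c_0 = \sqrt{\tfrac{2}{3\rho}(k_1 e^{k_2 D_0/2} + k_3)}}.
#' The viscoelastic contribution is \eqn{\Gamma/(A_0\sqrt{A})\,\partial A/
#' \partial t} with \eqn{\Gamma = 100 D + 400}.
#'
#' The default k constants are the literature-scale values
#' (k1 = 2e7 g/s2/cm, k2 = -22.5 1/cm, k3 = 8.65e5 g/s2/cm) that give
#' physiological wave speeds of several m/s in coronary-calibre vessels; all
#' three are exposed because published variants of the formula differ in
#' scaling.
#'
#' @param rho blood density, g/cm3
#' @param mu blood viscosity, Poise
#' @param k1,k2,k3 empirical stiffness constants (g/s2/cm, 1/cm, g/s2/cm)
#' @param P0 reference pressure, dyn/cm2 (conventionally the state's diastolic
#'   pressure)
#' @param Pcollapse collapse pressure, dyn/cm2 (default -10 mmHg)
#' @param Pext external pressure on the epicardial vessel wall, dyn/cm2
#'   (default 0; ventricular compression acts on the terminal beds, not the
#'   epicardial segments)
#' @param gamma_slope,gamma_intercept wall-viscosity law coefficients
#'   (Gamma = slope * D + intercept)
#' @param visc_coeff coefficient of the velocity-profile friction term
#'   (22 for coronary flow)
#' @return object of class `wall_params`
#' @export
wall_params <- function(rho = 1.05, mu = 0.04,
                        k1 = 2e7, k2 = -22.5, k3 = 8.65e5,
                        P0 = mmhg_to_cgs(74), Pcollapse = mmhg_to_cgs(-10),
                        Pext = 0, gamma_slope = 100, gamma_intercept = 400,
                        visc_coeff = 22) {
  if (rho <= 0) stop("rho must be > 0")
  if (k1 <= 0 || k3 <= 0) stop("k1 and k3 must be > 0")
  if (k2 >= 0) stop("k2 must be < 0")
  if (P0 <= Pcollapse) stop("P0 must exceed Pcollapse")
  structure(list(rho = rho, mu = mu, k1 = k1, k2 = k2, k3 = k3,
                 P0 = P0, Pcollapse = Pcollapse, Pext = Pext,
                 gamma_slope = gamma_slope, gamma_intercept = gamma_intercept,
                 visc_coeff = visc_coeff),
            class = "wall_params")
}

#' Empirical reference wave speed from vessel diameter
#'
#' \eqn{c_0(D_0) = \sqrt{\tfrac{2}{3\rho}(k_1 e^{k_2 D_0/2} + k_3)}};
#' monotonically decreasing in D0 (k2 < 0): smaller vessels are stiffer.
#'
#' @param D0 reference diameter, cm (vectorized)
#' @param params a `wall_params`
#' @return c0 in cm/s
#' @export
reference_wave_speed <- function(D0, params) {
  if (any(D0 <= 0)) stop("D0 must be > 0")
  sqrt(2 / (3 * params$rho) * (params$k1 * exp(params$k2 * D0 / 2) + params$k3))
}

#' Stiffness exponent of the tube law
#'
#' \eqn{b = 2\rho c_0^2 / (P_0 - P_{collapse})}.
#'
#' @param c0 reference wave speed, cm/s
#' @param params a `wall_params`
#' @return dimensionless exponent b
#' @export
stiffness_exponent <- function(c0, params) {
  if (params$P0 <= params$Pcollapse) stop("P0 must exceed Pcollapse")
  2 * params$rho * c0^2 / (params$P0 - params$Pcollapse)
}

#' Elastic transmural pressure of the tube law
#'
#' @param A current area, cm2
#' @param A0 reference area, cm2
#' @param c0 reference wave speed, cm/s
#' @param b stiffness exponent
#' @param params a `wall_params`
#' @return pressure P, dyn/cm2
#' @export
elastic_pressure <- function(A, A0, c0, b, params) {
  if (any(A <= 0) || any(A0 <= 0)) stop("areas must be > 0")
  params$P0 + params$Pext + 2 * params$rho * c0^2 / b * ((A / A0)^(b / 2) - 1)
}

#' Analytic inverse of the elastic tube law
#'
#' Returns the area at which `elastic_pressure` equals P.
#'
#' @param P pressure, dyn/cm2
#' @inheritParams elastic_pressure
#' @return area A, cm2
#' @export
inverse_area <- function(P, A0, c0, b, params) {
  arg <- 1 + b * (P - params$P0 - params$Pext) / (2 * params$rho * c0^2)
  if (any(arg <= 0))
    stop("pressure below collapse limit of the elastic law")
  A0 * arg^(2 / b)
}

#' Vessel compliance dA/dP of the elastic law
#'
#' Evaluated analytically: \eqn{C_a = A_0 (A/A_0)^{1-b/2} / (\rho c_0^2)}.
#' At A = A0 this reduces to the linearized value \eqn{A_0/(\rho c_0^2)}.
#'
#' @inheritParams elastic_pressure
#' @return compliance, cm2 per dyn/cm2
#' @export
compliance <- function(A, A0, c0, b, params) {
  if (any(A <= 0) || any(A0 <= 0)) stop("areas must be > 0")
  A0 * (A / A0)^(1 - b / 2) / (params$rho * c0^2)
}

#' Wall viscous coefficient
#'
#' Linear in the lumen diameter: Gamma = slope * D + intercept (defaults
#' 100 D + 400).
#'
#' @param D lumen diameter, cm
#' @param params a `wall_params`
#' @return Gamma (g/s/cm, CGS)
#' @export
wall_viscosity <- function(D, params) {
  params$gamma_slope * D + params$gamma_intercept
}

#' Viscoelastic pressure contribution
#'
#' \eqn{P_{visc} = \Gamma/(A_0\sqrt{A})\;\partial A/\partial t}: dissipative,
#' zero in steady state, same sign as dA/dt.
#'
#' @param A current area, cm2
#' @param dA_dt rate of area change, cm2/s
#' @param A0 reference area, cm2
#' @param Gamma wall viscous coefficient
#' @return pressure contribution, dyn/cm2
#' @export
viscoelastic_pressure <- function(A, dA_dt, A0, Gamma) {
  Gamma / (A0 * sqrt(A)) * dA_dt
}

#' Local (nonlinear) wave speed at area A
#'
#' \eqn{c(A) = \sqrt{A (\partial P/\partial A)/\rho} = c_0 (A/A_0)^{b/4}};
#' equals c0 at the reference state, tying the tube law to the empirical
#' wave-speed formula.
#'
#' @inheritParams elastic_pressure
#' @return wave speed, cm/s
#' @export
local_wave_speed <- function(A, A0, c0, b, params) {
  c0 * (A / A0)^(b / 4)
}
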