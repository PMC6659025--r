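#' Arrhenius temperature scaling of metabolic rates
#'
#' Enzymatically driven rates (standard and active metabolism, maximum
#' consumption) share a common temperature factor
#' \deqn{c(T) = \exp\!\left(\frac{E_a (T - T_0)}{b\,T\,T_0}\right)}
#' with temperatures in Kelvin and \eqn{b} the Boltzmann constant
#' (8.617e-5 eV/K). The factor equals 1 at the reference temperature and is
#' strictly increasing in T.
#'
#' @param T_c Temperature in degrees Celsius (vectorized).
#' @param thermal A [thermal_params()] block (or a `fish_params` bundle).
#' @return Dimensionless scaling factor(s).
#' @export
arrhenius_factor <- function(T_c, thermal) {
  thermal <- as_thermal(thermal)
  if (any(T_c <= -273.15)) stop("temperature below absolute zero", call. = FALSE)
  TK <- T_c + 273.15
  T0K <- thermal$T0 + 273.15
  exp(thermal$E_a * (TK - T0K) / (.kB * TK * T0K))
}

#' Ambient dissolved oxygen as a function of temperature
#'
#' Approximates the decline of dissolved oxygen in saltwater at 35 PSU as
#' \eqn{l\,e^{-d\,(T-5)}}, anchored at the concentration `l` at 5 C.
#'
#' @inheritParams arrhenius_factor
#' @return Concentration in mg/L.
#' @export
ambient_oxygen <- function(T_c, thermal) {
  thermal <- as_thermal(thermal)
  thermal$l * exp(-thermal$o2_decay * (T_c - 5))
}

#' Maximum oxygen supply level lambda(T)
#'
#' A flexible dome in temperature,
#' \deqn{\lambda(T) = \zeta\, x^{\eta}\, e^{\eta (1 - x)}, \quad
#'       x = \frac{T_{max} - T}{T_{max} - T_{opt}},}
#' which is zero at the lethal temperature, has its unique maximum
#' \eqn{\lambda(T_{opt}) = \zeta} at `T_opt`, and with `eta` near zero rises
#' almost monotonically up to `T_max`. The default parametrization is
#' normalized so the peak equals `zeta` exactly; `normalize = FALSE` drops
#' the \eqn{e^{\eta}} factor and gives the unnormalized scale
#' \eqn{\zeta x^\eta e^{-\eta x}} (the shape is identical). `exp_coef`
#' replaces the coefficient \eqn{\eta} inside the exponential, for
#' sensitivity checks such as re-using a metabolic exponent there; with any
#' `exp_coef != eta` the stationary point is no longer at `T_opt`.
#'
#' @inheritParams arrhenius_factor
#' @param normalize Scale so that `mos_level(T_opt) == zeta` (default TRUE).
#' @param exp_coef Coefficient inside the exponential; defaults to `eta`.
#' @return Supply level in g/y (per unit w^n).
#' @export
mos_level <- function(T_c, thermal, normalize = TRUE, exp_coef = NULL) {
  thermal <- as_thermal(thermal)
  if (any(T_c > thermal$T_max)) {
    stop("temperature above the lethal temperature T_max = ", thermal$T_max,
         call. = FALSE)
  }
  a <- exp_coef %||% thermal$eta
  x <- (thermal$T_max - T_c) / (thermal$T_max - thermal$T_opt)
  lam <- thermal$zeta * x^thermal$eta * exp(-a * x)
  if (normalize) lam <- lam * exp(thermal$eta)
  lam
}

#' Oxygen supply coefficient S_O2(T)
#'
#' The supply level [mos_level()] discounted by a saturating dependence on
#' ambient dissolved oxygen:
#' \deqn{S_{O_2}(T) = \lambda(T)\left(1 - e^{(C(T) - C_{crit})
#'       \log(0.5) / (C_{50} - C_{crit})}\right)}
#' with \eqn{C(T)} from [ambient_oxygen()]. Supply is zero at (or below) the
#' critical concentration and half of \eqn{\lambda(T)} at `C_50`. Total
#' supply for a fish of weight w is `oxygen_supply(T) * w^n`.
#'
#' @inheritParams mos_level
#' @return Supply coefficient in g O2-equivalents per year per unit w^n.
#' @export
oxygen_supply <- function(T_c, thermal, normalize = TRUE) {
  thermal <- as_thermal(thermal)
  lam <- mos_level(T_c, thermal, normalize = normalize)
  C <- ambient_oxygen(T_c, thermal)
  frac <- 1 - exp((C - thermal$C_crit) * log(0.5) /
                    (thermal$C_50 - thermal$C_crit))
  frac[C < thermal$C_crit] <- 0
  lam * frac
}

as_thermal <- function(x) {
  if (inherits(x, "fish_params")) x$thermal else x
}

as_traits <- function(x) {
  if (inherits(x, "fish_params")) x$traits else x
}
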