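#' Convert Celsius to Kelvin
#'
#' @param t_c Temperature(s) in degrees Celsius; must exceed absolute zero.
#' @return Temperature(s) in Kelvin.
#' @examples
#' celsius_to_kelvin(25)
#' @export
celsius_to_kelvin <- function(t_c) {
  if (!is.numeric(t_c) || any(!is.finite(t_c))) {
    stop("temperature must be finite and numeric", call. = FALSE)
  }
  if (any(t_c <= -273.15)) {
    stop("temperature at or below absolute zero (-273.15 C)", call. = FALSE)
  }
  t_c + 273.15
}

#' Convert Kelvin to Celsius
#'
#' @param t_k Temperature(s) in Kelvin; must be strictly positive.
#' @return Temperature(s) in degrees Celsius.
#' @export
kelvin_to_celsius <- function(t_k) {
  if (any(t_k <= 0)) stop("temperature in Kelvin must be positive", call. = FALSE)
  t_k - 273.15
}

trait_point <- function(t_k) {
  structure(list(temperature_K = t_k, temperature_C = t_k - 273.15),
            class = "trait_point")
}

#' @export
print.trait_point <- function(x, ...) {
  cat(sprintf("%.3f K (%.3f C)\n", x$temperature_K, x$temperature_C))
  invisible(x)
}

#' Temperature coefficient Q10
#'
#' The factor by which a rate changes over a 10-degree temperature increase:
#' \eqn{Q_{10} = (R_2/R_1)^{10/(T_2 - T_1)}}.  Dimensionless; over an
#' exactly 10-degree interval it equals the raw rate ratio.
#'
#' @param R1,R2 Rates at temperatures `T1` and `T2` (same units, > 0).
#' @param T1,T2 Temperatures in any consistent scale (Celsius or Kelvin);
#'   must differ.
#' @return A list of class `q10_result` with components `q10`, `R1`, `R2`,
#'   `T1`, `T2`.
#' @examples
#' q10(1, 2, 10, 20)$q10  # rate doubling over 10 degrees -> 2
#' @export
q10 <- function(R1, R2, T1, T2) {
  if (any(c(R1, R2) <= 0)) stop("rates must be strictly positive", call. = FALSE)
  if (T1 == T2) stop("temperatures must differ", call. = FALSE)
  structure(list(q10 = (R2 / R1)^(10 / (T2 - T1)),
                 R1 = R1, R2 = R2, T1 = T1, T2 = T2),
            class = "q10_result")
}

#' Arrhenius model parameters
#'
#' @param ln_A Natural log of the pre-exponential factor (log rate units).
#' @param E_A Activation energy, J mol^-1.
#' @return An `arrhenius_params` list.
#' @export
arrhenius_params <- function(ln_A, E_A) {
  stopifnot(is.finite(ln_A), is.finite(E_A))
  structure(list(ln_A = ln_A, E_A = E_A), class = "arrhenius_params")
}

#' MMRT model parameters
#'
#' Coefficients of the macromolecular rate theory curve.  `dH` and `dS` are
#' the enthalpy and entropy of activation *at the reference temperature*
#' `T0` and change with the choice of `T0`; `dCp`, the heat capacity of
#' activation, and the derived traits (temperature optimum, point of
#' maximum temperature sensitivity) do not.  Because assay rates are
#' activities (nmol L^-1 h^-1) rather than true first-order rate constants,
#' the unit mismatch with the \eqn{k_B T / h} prefactor is absorbed as a
#' constant offset into `dS`; `dS` values are therefore only comparable
#' within a fixed unit convention.
#'
#' @param dH Enthalpy of activation at `T0`, J mol^-1.
#' @param dS Entropy of activation at `T0`, J mol^-1 K^-1.
#' @param dCp Heat capacity of activation, J mol^-1 K^-1 (negative for
#'   concave-down rate curves).
#' @param T0 Reference temperature, K (default 298.15).
#' @return An `mmrt_params` list.
#' @export
mmrt_params <- function(dH, dS, dCp, T0 = 298.15) {
  stopifnot(is.finite(dH), is.finite(dS), is.finite(dCp), is.finite(T0), T0 > 0)
  structure(list(dH = unname(dH), dS = unname(dS), dCp = unname(dCp),
                 T0 = unname(T0)),
            class = "mmrt_params")
}

#' Arrhenius log rate
#'
#' \eqn{\ln k = \ln A - E_A / (R T)}; linear in \eqn{1/T}.
#'
#' @param p An [arrhenius_params()] object.
#' @param temp_k Temperature(s), K (> 0).
#' @param const Physical constants, see [phys_constants()].
#' @return Natural-log rate(s).
#' @export
arrhenius_ln_rate <- function(p, temp_k, const = phys_constants()) {
  if (any(temp_k <= 0)) stop("temperature in Kelvin must be positive", call. = FALSE)
  p$ln_A - p$E_A / (const$R * temp_k)
}

#' MMRT log rate
#'
#' The macromolecular rate theory curve
#' \deqn{\ln k = \ln\frac{k_B T}{h}
#'   - \frac{\Delta H^\ddagger + \Delta C_p^\ddagger (T - T_0)}{R T}
#'   + \frac{\Delta S^\ddagger + \Delta C_p^\ddagger (\ln T - \ln T_0)}{R}.}
#' At `T = T0` the heat-capacity terms vanish exactly and the expression
#' reduces to the two-term Eyring form.  Negative `dCp` produces a
#' concave-down curve with an interior rate maximum.
#'
#' @param p An [mmrt_params()] object.
#' @inheritParams arrhenius_ln_rate
#' @return Natural-log rate(s).
#' @export
mmrt_ln_rate <- function(p, temp_k, const = phys_constants()) {
  if (any(temp_k <= 0)) stop("temperature in Kelvin must be positive", call. = FALSE)
  log(const$kB_over_h * temp_k) -
    (p$dH + p$dCp * (temp_k - p$T0)) / (const$R * temp_k) +
    (p$dS + p$dCp * (log(temp_k) - log(p$T0))) / const$R
}

#' Temperature derivative of the MMRT log rate
#'
#' \eqn{d\ln k/dT = 1/T + (\Delta H^\ddagger - \Delta C_p^\ddagger T_0)/(R T^2)
#'   + \Delta C_p^\ddagger/(R T)}; zero at the temperature optimum.
#'
#' @inheritParams mmrt_ln_rate
#' @return Slope(s) of ln rate with temperature, K^-1.
#' @export
mmrt_dlnk_dT <- function(p, temp_k, const = phys_constants()) {
  if (any(temp_k <= 0)) stop("temperature in Kelvin must be positive", call. = FALSE)
  1 / temp_k + (p$dH - p$dCp * p$T0) / (const$R * temp_k^2) +
    p$dCp / (const$R * temp_k)
}

# second derivative of ln k with T; needed for the inflection point of k(T)
mmrt_d2lnk_dT2 <- function(p, temp_k, const = phys_constants()) {
  -1 / temp_k^2 - 2 * (p$dH - p$dCp * p$T0) / (const$R * temp_k^3) -
    p$dCp / (const$R * temp_k^2)
}

#' Temperature optimum of an MMRT curve
#'
#' Closed-form root of [mmrt_dlnk_dT()]:
#' \eqn{T_{opt} = (\Delta C_p^\ddagger T_0 - \Delta H^\ddagger)/(R + \Delta C_p^\ddagger)},
#' the unique maximizer of the log rate.  Requires `dCp < -R`, otherwise
#' the curve has no interior maximum.
#'
#' @inheritParams mmrt_ln_rate
#' @return A `trait_point` (temperature in both K and Celsius).
#' @examples
#' topt(mmrt_params(dH = 50000, dS = 0, dCp = -5000))
#' @export
topt <- function(p, const = phys_constants()) {
  if (p$dCp >= -const$R) {
    stop("no finite optimum: dCp must be below -R", call. = FALSE)
  }
  trait_point((p$dCp * p$T0 - p$dH) / (const$R + p$dCp))
}

# bracket-safe bisection; |interval| <= tol on exit
bisect_root <- function(f, lower, upper, tol = 1e-6) {
  fl <- f(lower)
  fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) {
    stop("no sign change in the bracket", call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (fl * fm < 0) {
      upper <- mid
    } else {
      lower <- mid
      fl <- fm
    }
  }
  (lower + upper) / 2
}

#' Point of maximum temperature sensitivity of an MMRT curve
#'
#' The temperature where \eqn{dk/dT} is greatest, i.e. the inflection point
#' of \eqn{k(T)} on the rising limb.  With \eqn{g = d\ln k/dT}, it is the
#' root of \eqn{g(T)^2 + g'(T) = 0} on `(bracket_low, Topt)`, located by
#' bisection to 1e-6 K.  Always strictly below the temperature optimum.
#'
#' @inheritParams mmrt_ln_rate
#' @param bracket_low Lower bracket for the root search, K.  The default
#'   250 K is well below any assay temperature and brackets the inflection
#'   for curvatures typical of enzyme assays.
#' @return A `trait_point`.
#' @export
tsmax <- function(p, const = phys_constants(), bracket_low = 250) {
  t_opt <- topt(p, const)$temperature_K
  if (bracket_low >= t_opt) {
    stop("bracket_low must lie below the temperature optimum", call. = FALSE)
  }
  f <- function(t_k) {
    mmrt_dlnk_dT(p, t_k, const)^2 + mmrt_d2lnk_dT2(p, t_k, const)
  }
  root <- tryCatch(bisect_root(f, bracket_low, t_opt, tol = 1e-6),
                   error = function(e) {
                     stop("no TSmax in range (", bracket_low, ", ",
                          round(t_opt, 2), ") K", call. = FALSE)
                   })
  trait_point(root)
}
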