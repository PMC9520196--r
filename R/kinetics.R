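#' Michaelis-Menten rate
#'
#' Saturating rate law `Vmax * S / (Km + S)` used for cellulase activity and
#' membrane-transporter uptake of glucose and amino acids. Bounded in
#' `[0, Vmax)`, strictly increasing in the substrate concentration `S` and
#' strictly decreasing in the half-saturation constant `Km` for `S > 0`.
#'
#' @param Vmax Maximum specific rate (>= 0). Recycled against `S`.
#' @param S Substrate concentration (>= 0).
#' @param Km Half-saturation constant (> 0).
#' @return Numeric vector of rates, same units as `Vmax`.
#' @examples
#' michaelis_menten_rate(1, S = 0.5, Km = 0.5) # half-saturation: 0.5
#' michaelis_menten_rate(2, S = 3, Km = 1)     # 1.5
#' @export
michaelis_menten_rate <- function(Vmax, S, Km) {
  if (any(!is.finite(Vmax)) || any(Vmax < 0)) {
    abort("`Vmax` must be finite and non-negative.",
          class = "bq_parameter_error")
  }
  if (any(!is.finite(S)) || any(S < 0)) {
    abort("Substrate concentration `S` must be finite and non-negative.",
          class = "bq_parameter_error")
  }
  if (any(!is.finite(Km)) || any(Km <= 0)) {
    abort("`Km` must be finite and strictly positive.",
          class = "bq_parameter_error")
  }
  Vmax * S / (Km + S)
}

#' Monod fraction
#'
#' Dimensionless saturation fraction `S / (K + S)` in `[0, 1)`, used for the
#' glucose dependence of amino-acid leakage and for the growth-limitation
#' terms.
#'
#' @param S Concentration (>= 0).
#' @param K Half-saturation constant (> 0).
#' @return Numeric vector of fractions in `[0, 1)`.
#' @examples
#' monod_fraction(9, 1) # 0.9
#' @export
monod_fraction <- function(S, K) {
  michaelis_menten_rate(1, S, K)
}
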