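# Doppler echocardiography pressure estimates: modified Bernoulli gradient,
# PA systolic pressure, and the linear conversion to mean PA pressure.

#' Tricuspid gradient by the modified Bernoulli equation
#'
#' TG = 4 x TRJV^2, with the tricuspid regurgitant jet velocity in m/s and
#' the gradient in mmHg.
#'
#' @param trjv tricuspid regurgitant jet velocity, m/s (>= 0).
#' @return pressure gradient, mmHg.
#' @export
#' @examples
#' tricuspid_gradient(3)  # 36 mmHg
tricuspid_gradient <- function(trjv) {
  if (any(!is.finite(trjv)) || any(trjv < 0)) {
    rhcmr_error("TRJV must be non-negative (m/s)", "rhcmr_invalid_echo")
  }
  4 * trjv^2
}

#' Pulmonary-artery systolic pressure estimate
#'
#' Tricuspid gradient plus the estimated right atrial pressure (from IVC
#' diameter and respiratory variation, supplied as an input).
#'
#' @inheritParams tricuspid_gradient
#' @param rap estimated right atrial pressure, mmHg (>= 0).
#' @return PA systolic pressure, mmHg.
#' @export
pa_systolic_pressure <- function(trjv, rap) {
  if (any(!is.finite(rap)) || any(rap < 0)) {
    rhcmr_error("RAP estimate must be non-negative (mmHg)",
                "rhcmr_invalid_echo")
  }
  tricuspid_gradient(trjv) + rap
}

#' Mean PA pressure from the systolic estimate
#'
#' mPAP = 0.61 x PASP + 2 mmHg, the standard linear conversion used to
#' compare Doppler estimates with catheter-measured mean pressure.
#'
#' @param pasp PA systolic pressure, mmHg.
#' @return estimated mean PA pressure, mmHg.
#' @export
#' @examples
#' mpap_from_echo(41)  # 27.01
mpap_from_echo <- function(pasp) {
  0.61 * pasp + 2
}

#' Echo-estimated mean PA pressure from TRJV and RAP
#'
#' Composition of [tricuspid_gradient()], [pa_systolic_pressure()] and
#' [mpap_from_echo()]; strictly increasing in TRJV for fixed RAP.
#'
#' @inheritParams pa_systolic_pressure
#' @return estimated mean PA pressure, mmHg.
#' @export
echo_mpap <- function(trjv, rap) {
  mpap_from_echo(pa_systolic_pressure(trjv, rap))
}
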