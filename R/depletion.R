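# Radiolytic oxygen depletion during the irradiation pulse.
#
# During beam-on, oxygen tension falls linearly at rate S_ROD until it
# reaches zero and stays there; rediffusion during the (sub-second) pulse
# is neglected, so every radius evolves independently:
#     p(r, t) = max(ps(r) - S_ROD * t, 0).

#' Depletion rate from the dose-normalised depletion coefficient
#'
#' The radiolytic depletion rate scales linearly with dose rate:
#' \code{S_ROD = L_ROD * dose_rate}. At conventional dose rates the product
#' is negligible next to metabolic consumption; at FLASH dose rates it
#' dominates the oxygen dynamics.
#'
#' @param L_ROD Oxygen depleted per unit dose (mmHg/Gy, >= 0).
#' @param dose_rate Dose rate (Gy/s, >= 0).
#' @return Depletion rate in mmHg/s.
#' @examples
#' srod_from_lrod(0.17, 90)   # 15.3 mmHg/s, the measured in-vitro value
#' srod_from_lrod(1.78, 90)   # 160.2 mmHg/s
#' @export
srod_from_lrod <- function(L_ROD, dose_rate) {
  check_nonneg(L_ROD, "L_ROD")
  check_nonneg(dose_rate, "dose_rate")
  L_ROD * dose_rate
}

#' Oxygen depletion field over a steady-state profile
#'
#' Combines a steady-state profile with a depletion rate into a queryable
#' space-time oxygen field. The per-radius depletion time is
#' \code{ps(r) / S_ROD} (infinite where \code{S_ROD = 0} or \code{ps = 0}
#' never falls).
#'
#' @param profile An \code{\link{solve_steady_oxygen}} result.
#' @param S_ROD Depletion rate (mmHg/s); defaults to the rate stored in the
#'   profile's parameters.
#' @return An object of class \code{depletion_field}.
#' @export
depletion_field <- function(profile, S_ROD = profile$params$S_ROD) {
  stopifnot(inherits(profile, "oxygen_profile"))
  check_nonneg(S_ROD, "S_ROD")
  structure(list(profile = profile, S_ROD = S_ROD),
            class = "depletion_field")
}

#' @export
print.depletion_field <- function(x, ...) {
  cat(sprintf("Oxygen depletion field: S_ROD = %g mmHg/s over profile with r0 = %.4g mm\n",
              x$S_ROD, x$profile$r0_mm))
  invisible(x)
}

#' Oxygen tension during the pulse
#'
#' @param field A \code{\link{depletion_field}}.
#' @param r Radius in mm (vectorised), inside \code{[0, H]}.
#' @param t Time since beam-on in seconds (vectorised, >= 0).
#' @return \code{max(ps(r) - S_ROD * t, 0)} in mmHg. \code{r} and \code{t}
#'   are recycled to a common length.
#' @examples
#' prof <- solve_steady_oxygen(flash_params(S_ROD = 160))
#' f <- depletion_field(prof)
#' oxygen_at(f, r = 0.4, t = c(0, 0.05, 0.111))
#' @export
oxygen_at <- function(field, r, t) {
  stopifnot(inherits(field, "depletion_field"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  ps <- field$profile$ps_fun(r)            # errors on r outside [0, H]
  pmax(ps - field$S_ROD * t, 0)
}

#' Per-radius depletion time
#'
#' Time at which the tension at radius \code{r} reaches zero;
#' \code{Inf} where it never does, \code{0} inside the anoxic core.
#'
#' @inheritParams oxygen_at
#' @return Depletion time in seconds.
#' @export
depletion_time <- function(field, r) {
  stopifnot(inherits(field, "depletion_field"))
  ps <- field$profile$ps_fun(r)
  ifelse(ps == 0, 0,
         if (field$S_ROD > 0) ps / field$S_ROD else Inf)
}
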