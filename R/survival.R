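# OER-modified linear-quadratic survival, conventional and FLASH.
#
# The instantaneous kill rate during irradiation is
#     dN/N = -[alpha(p) + 2 beta(p) D(t)] * Ddot dt  (+ ROS relief term),
# with alpha(p) = alpha0 * OER(p), beta(p) = beta0 * OER(p)^2 and
# OER(p) = (m p + K)/(p + K). Under conventional delivery oxygen stays at
# its steady state, the coefficients are constant and the integral
# collapses to the familiar log SF = -alpha D - beta D^2. Under FLASH the
# tension p(r, t) falls during the pulse, so the log survival is the time
# integral of the kill rate over the beam-on window [0, T], T = D / Ddot,
# plus, when the oxidative-stress term is on, the sigmoid relief
# kr / (1 + exp(a + b dROS(t))) which credits the lower ROS level under
# FLASH. Log survival here is natural log; radial summaries convert to
# log10 at the reporting layer.

#' Oxygen enhancement ratio
#'
#' \code{OER(p) = (m p + K) / (p + K)}: equal to 1 for anoxic cells,
#' saturating at \code{m} for fully oxygenated cells, with half-saturation
#' tension \code{K}. The \code{"inverse"} orientation
#' \code{(m K + p)/(K + p)} (maximal sensitisation at zero oxygen) is kept
#' only for sensitivity analysis.
#'
#' @param p Oxygen tension (mmHg, vectorised, >= 0).
#' @param sp A \code{\link{survival_params}} object.
#' @return OER values (dimensionless).
#' @examples
#' oer(0, survival_params())      # 1
#' oer(1.9, survival_params())    # (m + 1)/2 at p = K
#' @export
oer <- function(p, sp) {
  stopifnot(inherits(sp, "survival_params"))
  if (any(p < 0)) stop("oxygen tension must be non-negative", call. = FALSE)
  if (identical(sp$oer_orientation, "inverse"))
    (sp$m * sp$K + p) / (sp$K + p)
  else
    (sp$m * p + sp$K) / (p + sp$K)
}

#' Oxygen-dependent LQ coefficients
#'
#' \code{alpha(p) = alpha0 * OER(p)}, \code{beta(p) = beta0 * OER(p)^2}.
#'
#' @inheritParams oer
#' @return A list with vectors \code{alpha} (1/Gy) and \code{beta} (1/Gy^2).
#' @export
lq_coefficients <- function(p, sp) {
  o <- oer(p, sp)
  list(alpha = sp$alpha0 * o, beta = sp$beta0 * o^2)
}

#' Conventional-delivery log survival (closed form)
#'
#' At conventional dose rates the oxygen tension is effectively frozen at
#' its steady state, so log SF = \code{-alpha(ps) D - beta(ps) D^2}.
#'
#' @param ps Steady-state oxygen tension (mmHg, vectorised).
#' @param dose Total dose (Gy, >= 0).
#' @param sp A \code{\link{survival_params}} object.
#' @return Natural-log surviving fraction (<= 0).
#' @examples
#' conv_log_survival(0, 10, survival_params())   # -48.4 with the defaults
#' @export
conv_log_survival <- function(ps, dose, sp) {
  check_nonneg(dose, "dose")
  lq <- lq_coefficients(ps, sp)
  -lq$alpha * dose - lq$beta * dose^2
}

#' Sigmoid oxidative-stress relief rate
#'
#' \code{kr / (1 + exp(a + b * dros))}: the survival credit per unit time
#' for the reduced ROS level under FLASH. Designed to be essentially zero
#' at \code{dros = 0} (for the default constants,
#' \code{kr/(1 + e^8)} which is about 1e-5 /s) and to saturate at \code{kr}
#' for a large ROS deficit; monotone decreasing in \code{dros}.
#'
#' @param dros FLASH-minus-CONV ROS difference (uM, vectorised; <= 0 in
#'   this model).
#' @param sp A \code{\link{survival_params}} object.
#' @return Relief rate in 1/s.
#' @examples
#' oxidative_relief(0, survival_params())     # ~1e-5
#' oxidative_relief(-1, survival_params())    # ~kr
#' @export
oxidative_relief <- function(dros, sp) {
  stopifnot(inherits(sp, "survival_params"))
  sp$kr / (1 + exp(sp$a + sp$b * dros))
}

#' FLASH log survival at one radius
#'
#' Integrates the kill rate over the beam-on window \code{[0, T]},
#' \code{T = dose / dose_rate}, with the tension following the linear
#' depletion ramp, by adaptive quadrature with a forced breakpoint at the
#' depletion time (where the integrand's derivative jumps). With
#' \code{include_ros = TRUE} (and \code{kr > 0}) the sigmoid
#' oxidative-stress relief driven by the closed-form dROS trajectory is
#' added; it raises log survival because dROS <= 0. The result is capped at
#' 0 (SF cannot exceed 1), with a warning when the cap binds.
#'
#' @param ps Steady-state oxygen tension at the radius (mmHg, scalar).
#' @param dose Total dose (Gy).
#' @param dose_rate Dose rate (Gy/s, > 0).
#' @param S_ROD Radiolytic depletion rate (mmHg/s).
#' @param sp A \code{\link{survival_params}} object.
#' @param cell A \code{\link{cell_params}} object; required when the ROS
#'   term is active.
#' @param include_ros Include the sigmoid ROS term (default TRUE).
#' @param rel_tol,abs_tol Quadrature tolerances.
#' @return Natural-log surviving fraction (scalar, <= 0).
#' @export
flash_log_survival <- function(ps, dose, dose_rate, S_ROD, sp,
                               cell = NULL, include_ros = TRUE,
                               rel_tol = 1e-10, abs_tol = 1e-12) {
  stopifnot(inherits(sp, "survival_params"), length(ps) == 1L)
  check_nonneg(dose, "dose"); check_pos(dose_rate, "dose_rate")
  check_nonneg(S_ROD, "S_ROD"); check_nonneg(ps, "ps")
  if (dose == 0) return(0)
  T_on <- dose / dose_rate
  td <- if (S_ROD > 0 && ps > 0) ps / S_ROD else Inf
  brk <- sort(unique(c(0, min(td, T_on), T_on)))

  kill_rate <- function(t) {
    p <- pmax(ps - S_ROD * t, 0)
    lq <- lq_coefficients(p, sp)
    -(lq$alpha + 2 * lq$beta * dose_rate * t) * dose_rate
  }
  total <- quad_segments(kill_rate, brk, rel_tol, abs_tol)

  use_ros <- include_ros && sp$kr > 0
  if (use_ros) {
    if (is.null(cell))
      stop("cell parameters are required for the ROS term", call. = FALSE)
    ros_rate <- function(t)
      oxidative_relief(delta_ros_closed(ps, cell, S_ROD, t), sp)
    total <- total + quad_segments(ros_rate, brk, rel_tol, abs_tol)
  }
  if (total > 0) {
    if (total > 1e-9)
      warning("log survival clipped at 0 (ROS relief exceeded the kill term)",
              call. = FALSE)
    total <- 0
  }
  total
}

quad_segments <- function(f, breaks, rel_tol, abs_tol) {
  tot <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    if (breaks[i + 1L] > breaks[i]) {
      q <- stats::integrate(f, breaks[i], breaks[i + 1L],
                            rel.tol = rel_tol, abs.tol = abs_tol,
                            stop.on.error = FALSE)
      if (!q$message %in% "OK")
        stop("quadrature failed on [", breaks[i], ", ", breaks[i + 1L],
             "]: ", q$message, " (abs.error ", q$abs.error, ")",
             call. = FALSE)
      tot <- tot + q$value
    }
  }
  tot
}

#' Piecewise-analytic FLASH depletion-kill log survival (oracle)
#'
#' Closed-form antiderivative of the depletion kill term used to
#' cross-check the adaptive quadrature in \code{\link{flash_log_survival}}.
#' While the tension ramps down linearly, substituting
#' \code{u = p + K} makes \code{OER = m - K(m-1)/u} and both LQ terms
#' rational in \code{u}, so the time integral reduces to elementary
#' functions; after full depletion the coefficients are constant. The ROS
#' sigmoid term is not included (it has no elementary antiderivative).
#'
#' @inheritParams flash_log_survival
#' @return Natural-log surviving fraction from the depletion kill term
#'   alone.
#' @export
flash_log_survival_analytic <- function(ps, dose, dose_rate, S_ROD, sp) {
  stopifnot(inherits(sp, "survival_params"), length(ps) == 1L)
  check_nonneg(dose, "dose"); check_pos(dose_rate, "dose_rate")
  check_nonneg(S_ROD, "S_ROD"); check_nonneg(ps, "ps")
  if (identical(sp$oer_orientation, "inverse"))
    stop("analytic form implemented for the standard OER orientation only",
         call. = FALSE)
  if (dose == 0) return(0)
  T_on <- dose / dose_rate
  m <- sp$m; K <- sp$K; cc <- K * (m - 1)
  a0 <- sp$alpha0; b0 <- sp$beta0; Ddot <- dose_rate

  if (S_ROD == 0 || ps == 0) {
    # constant tension: plain LQ at that tension
    return(conv_log_survival(ps, dose, sp))
  }
  t1 <- min(ps / S_ROD, T_on)
  u0 <- ps + K
  u1 <- ps + K - S_ROD * t1

  # ramp segment [0, t1]:
  # int OER dt       = (m (u0 - u1) - cc log(u0/u1)) / S_ROD
  A_int <- (m * (u0 - u1) - cc * log(u0 / u1)) / S_ROD
  # int t OER^2 dt   = -(G(u1) - G(u0)) / S_ROD^2, G the antiderivative of
  # (u0 - u)(m^2 - 2 m cc / u + cc^2 / u^2) in u
  G <- function(u)
    u0 * m^2 * u - 2 * m * cc * u0 * log(u) - cc^2 * u0 / u -
      m^2 * u^2 / 2 + 2 * m * cc * u - cc^2 * log(u)
  B_int <- -(G(u1) - G(u0)) / S_ROD^2

  total <- -a0 * Ddot * A_int - 2 * b0 * Ddot^2 * B_int
  if (t1 < T_on)                            # anoxic tail, OER = 1
    total <- total - a0 * Ddot * (T_on - t1) - b0 * Ddot^2 * (T_on^2 - t1^2)
  total
}
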