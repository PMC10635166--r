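# FLASH-minus-CONV difference in reactive oxygen species, dROS(r, t).
#
# ROS is produced proportionally to the local oxygen concentration and
# degraded at a first-order rate k_ROS. Subtracting the CONV balance (where
# oxygen stays at its steady state ps) from the FLASH balance leaves a
# linear ODE for the difference alone, driven by the oxygen deficit:
#     d(dROS)/dt = cp * (p(r,t) - ps(r))_uM - k_ROS * dROS,   dROS(0) = 0.
# The forcing is expressed in uM (0.77 mmHg per uM); with the depletion
# model it is a downward linear ramp -cp * s * t until the depletion time
# td = ps / S_ROD, constant -cp * ps_uM afterwards, which integrates in
# closed form. dROS <= 0 throughout: FLASH produces less ROS than CONV.

#' Closed-form FLASH-minus-CONV ROS difference
#'
#' Exact solution of the linear ROS-difference ODE under linear oxygen
#' depletion, evaluated at one radius for a vector of times. On the ramp
#' segment (\code{t <= td}) the solution is
#' \code{-(cp*s/k) * t + (cp*s/k^2) * (1 - exp(-k t))} with \code{s} the
#' depletion rate in uM/s; afterwards it relaxes exponentially towards the
#' full-depletion fixed point \code{-cp * ps_uM / k}.
#'
#' @param ps Steady-state oxygen tension at the radius of interest (mmHg),
#'   scalar.
#' @param cell A \code{\link{cell_params}} object (uses \code{cp},
#'   \code{k_ROS}).
#' @param S_ROD Depletion rate (mmHg/s).
#' @param t Times since beam-on (s, vectorised, >= 0).
#' @return dROS in uM (non-positive).
#' @examples
#' delta_ros_closed(ps = 30, cell_params("healthy"), S_ROD = 15.3,
#'                  t = c(0, 0.05, 0.111))
#' @export
delta_ros_closed <- function(ps, cell, S_ROD, t) {
  stopifnot(inherits(cell, "cell_params"))
  check_nonneg(ps, "ps"); check_nonneg(S_ROD, "S_ROD")
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  k <- cell$k_ROS
  if (k <= 0) stop("k_ROS must be > 0", call. = FALSE)
  cp <- cell$cp
  if (cp == 0 || S_ROD == 0 || ps == 0) return(rep(0, length(t)))

  s_uM <- S_ROD / MMHG_PER_UM              # depletion rate in uM/s
  ps_uM <- ps / MMHG_PER_UM
  td <- ps / S_ROD

  ramp <- function(tt) -cp * s_uM * (tt / k - (1 - exp(-k * tt)) / k^2)
  y_td <- ramp(td)
  fix <- -cp * ps_uM / k                   # constant-forcing fixed point
  ifelse(t <= td,
         ramp(t),
         fix + (y_td - fix) * exp(-k * (t - td)))
}

#' ROS difference at a radius of a profile
#'
#' Convenience wrapper of \code{\link{delta_ros_closed}} that reads the
#' steady-state tension off an oxygen profile.
#'
#' @param profile An \code{oxygen_profile}.
#' @inheritParams delta_ros_closed
#' @param r Radius (mm, scalar).
#' @return Object of class \code{ros_trajectory}: list with \code{r_mm},
#'   \code{t}, \code{delta_ros} (uM) and the cell parameters.
#' @export
delta_ros_at <- function(profile, cell, S_ROD, r, t) {
  stopifnot(inherits(profile, "oxygen_profile"), length(r) == 1L)
  ps <- profile$ps_fun(r)
  structure(list(r_mm = r, t = t,
                 delta_ros = delta_ros_closed(ps, cell, S_ROD, t),
                 ps = ps, S_ROD = S_ROD, cell = cell),
            class = "ros_trajectory")
}

#' @export
print.ros_trajectory <- function(x, ...) {
  cat(sprintf("dROS trajectory at r = %g mm (ps = %.4g mmHg, S_ROD = %g mmHg/s, cell '%s')\n",
              x$r_mm, x$ps, x$S_ROD, x$cell$label))
  cat(sprintf("  %d time points on [%g, %g] s; final dROS = %.6g uM\n",
              length(x$t), min(x$t), max(x$t),
              x$delta_ros[length(x$delta_ros)]))
  invisible(x)
}

#' @export
as.data.frame.ros_trajectory <- function(x, ...) {
  data.frame(t_s = x$t, delta_ros_uM = x$delta_ros)
}

#' Numerically integrated ROS difference (oracle)
#'
#' Independent check of \code{\link{delta_ros_closed}}: integrates the same
#' ODE with an adaptive Runge-Kutta scheme (LSODA via \pkg{deSolve},
#' relative tolerance 1e-10) against the piecewise-linear oxygen forcing.
#'
#' @inheritParams delta_ros_closed
#' @param t_grid Increasing time grid starting at 0 (s).
#' @return dROS at each grid time (uM).
#' @export
delta_ros_numeric <- function(ps, cell, S_ROD, t_grid) {
  stopifnot(inherits(cell, "cell_params"))
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at 0", call. = FALSE)
  cp <- cell$cp; k <- cell$k_ROS
  deriv <- function(t, y, parms) {
    p <- max(ps - S_ROD * t, 0)
    list((cp * (p - ps) / MMHG_PER_UM) - k * y)
  }
  td <- if (S_ROD > 0 && ps > 0) ps / S_ROD else Inf
  # hand the integrator the forcing breakpoint so it does not step over it
  times <- sort(unique(c(t_grid, if (is.finite(td) && td < max(t_grid)) td)))
  out <- deSolve::ode(y = 0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-16)
  out[match(t_grid, out[, 1]), 2]
}
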