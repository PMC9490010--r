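# EMG-driven forward chain: excitation scaling -> delayed first-order
# activation dynamics -> activation nonlinearity -> rigid-tendon Hill-type
# muscle force -> net joint moments through the geometry's moment arms.

#' Activation dynamics rate constants
#'
#' `c1 = 1/tau_act - 1/tau_dact`, `c2 = 1/tau_dact`, with the deactivation
#' time constant tied to the activation one as `tau_dact = 4 * tau_act`.
#'
#' @param tau_act activation time constant(s), seconds, > 0.
#' @return list with numeric `c1` and `c2` (1/s).
#' @export
compute_c_constants <- function(tau_act) {
  if (any(tau_act <= 0)) stop("tau_act must be positive")
  c2 <- 1 / (4 * tau_act)
  list(c1 = 1 / tau_act - c2, c2 = c2)
}

#' First-order activation dynamics with electromechanical delay
#'
#' Solves `du/dt = (c1 * e(t - d) + c2) * (e(t - d) - u)` on the regular
#' frame grid. The excitation is delayed by `d` seconds (linear
#' interpolation), and the ODE is integrated with the exact update for
#' piecewise-constant excitation, which is unconditionally stable. `u` is
#' initialised at the delayed excitation of the first (pre-)frame.
#'
#' @param e frames x muscles matrix of excitations in `[0, 1]`.
#' @param tau_act activation time constant(s), seconds (scalar or
#'   per-muscle).
#' @param d electromechanical delay(s), seconds, in `[0, 0.1]`.
#' @param dt frame spacing, seconds.
#' @param n_pre number of pre-frames available before the cycle; the delay
#'   must not exceed `n_pre * dt`.
#' @return frames x muscles matrix of neural activations `u`.
#' @export
activation_dynamics <- function(e, tau_act, d, dt, n_pre = 20L) {
  e <- as.matrix(e)
  m <- ncol(e)
  tau_act <- rep_len(tau_act, m)
  d <- rep_len(d, m)
  if (any(d < 0)) stop("delay must be non-negative")
  if (any(d > n_pre * dt + 1e-12))
    stop("delay ", max(d), " s exceeds the pre-frame buffer (",
         n_pre * dt, " s)")
  cc <- compute_c_constants(tau_act)
  out <- .activation_dynamics_cpp(e, d, cc$c1, cc$c2, dt)$u
  dimnames(out) <- dimnames(e)
  out
}

#' Default activation-nonlinearity curve constants
#'
#' The nonlinear bracket `g1 * g2^((u + g3)^g4) + g5 + 1` maps `[0, 1]` to
#' `[0, 1]` monotonically with `a(0) = 0` and `a(1) = 1`. The shipped
#' constants (`g1 = 1/9, g2 = 10, g3 = 0, g4 = 2, g5 = -10/9`) give the
#' convex map `(10^(u^2) - 1) / 9`.
#'
#' @return named numeric vector `g1..g5`.
#' @export
default_g_constants <- function() {
  c(g1 = 1 / 9, g2 = 10, g3 = 0, g4 = 2, g5 = -10 / 9)
}

#' Activation nonlinearity
#'
#' `a = (1 - c3) * u + c3 * [g1 * g2^((u + g3)^g4) + g5 + 1]`. With
#' `c3 = 0` the map is the identity; larger `c3` blends in the nonlinear
#' bracket, which is constrained by the `g` constants to fix `a(0) = 0` and
#' `a(1) = 1`.
#'
#' @param u frames x muscles neural activations in `[0, 1]`.
#' @param c3 activation nonlinearity constant(s) in `[0, 1)` (scalar or
#'   per-muscle).
#' @param g curve constants (default [default_g_constants()]).
#' @return matrix of muscle activations `a`.
#' @export
activation_nonlinearity <- function(u, c3, g = default_g_constants()) {
  if (any(c3 < 0) || any(c3 >= 1))
    stop("c3 must be in [0, 1)")
  u <- as.matrix(u)
  c3 <- matrix(rep_len(c3, ncol(u)), nrow(u), ncol(u), byrow = TRUE)
  bracket <- g[["g1"]] * g[["g2"]]^((u + g[["g3"]])^g[["g4"]]) +
    g[["g5"]] + 1
  (1 - c3) * u + c3 * bracket
}

#' Default Hill-model normalised force curves
#'
#' * active force-length: Gaussian `fl(l) = exp(-(l - 1)^2 / 0.45)`;
#' * force-velocity: Hill hyperbola on the concentric side (shortening is
#'   negative normalised velocity; `fv(-1) = 0`, `fv(0) = 1`) with a
#'   C1-continuous saturating eccentric branch (asymptote 1.4);
#' * passive force-length: zero at or below optimal length, exponential
#'   above, normalised to 1 at `l = 1.7`.
#'
#' Any list with elements `fl`, `fv`, `fp` (vectorised functions of the
#' normalised fiber length / velocity) can be supplied wherever a curve set
#' is accepted.
#'
#' @param fl_gamma width of the Gaussian active force-length curve
#'   (default 0.45 in normalised-length units).
#' @return list of functions `fl`, `fv`, `fp`.
#' @export
default_muscle_curves <- function(fl_gamma = 0.45) {
  force(fl_gamma)
  structure(native = TRUE, fl_gamma = fl_gamma, .Data = list(
    fl = function(lm) exp(-(lm - 1)^2 / fl_gamma),
    fv = function(vm) {
      conc <- (1 + pmax(vm, -1)) / (1 - 4 * pmin(vm, 0))
      ecc <- 1 + 0.4 * vm / (vm + 0.08)
      ifelse(vm < 0, conc, ecc)
    },
    fp = function(lm) ifelse(lm > 1, expm1(4 * (lm - 1)) / expm1(4 * 0.7), 0)
  ))
}

#' Normalised fiber kinematics under the rigid-tendon assumption
#'
#' With a rigid tendon the fiber accounts for all muscle-tendon length
#' change beyond the tendon slack length: `l = (lMT - lsT) / loM` and
#' `v = vMT / (10 * loM)` (maximum shortening velocity of 10 optimal fiber
#' lengths per second; shortening is negative).
#'
#' @param lmt muscle-tendon length(s), m.
#' @param vmt muscle-tendon velocity(ies), m/s.
#' @param lo optimal fiber length(s), m, > 0.
#' @param ls tendon slack length(s), m.
#' @return list with `l` (normalised fiber length) and `v` (normalised
#'   fiber velocity).
#' @export
normalized_fiber_kinematics <- function(lmt, vmt, lo, ls) {
  if (any(lo <= 0)) stop("optimal fiber length must be positive")
  if (is.matrix(lmt)) {
    lo <- matrix(rep_len(lo, ncol(lmt)), nrow(lmt), ncol(lmt), byrow = TRUE)
    ls <- matrix(rep_len(ls, ncol(lmt)), nrow(lmt), ncol(lmt), byrow = TRUE)
  }
  list(l = (lmt - ls) / lo, v = vmt / (10 * lo))
}

#' Rigid-tendon Hill-type muscle force
#'
#' `F = Fmax * (a * fl(l) * fv(v) + fp(l)) * cos(alpha)`.
#'
#' @param a activation(s) in `[0, 1]`.
#' @param l normalised fiber length(s).
#' @param v normalised fiber velocity(ies).
#' @param fmax maximum isometric force(s), N.
#' @param alpha pennation angle(s), rad.
#' @param curves curve set (default [default_muscle_curves()]).
#' @return force(s), N.
#' @export
muscle_force <- function(a, l, v, fmax, alpha = 0,
                         curves = default_muscle_curves()) {
  if (is.matrix(a)) {
    fmax <- matrix(rep_len(fmax, ncol(a)), nrow(a), ncol(a), byrow = TRUE)
    alpha <- matrix(rep_len(alpha, ncol(a)), nrow(a), ncol(a), byrow = TRUE)
  }
  fmax * (a * curves$fl(l) * curves$fv(v) + curves$fp(l)) * cos(alpha)
}

#' Net joint moments from muscle forces and moment arms
#'
#' `M[, d] = sum_m F[, m] * r[, m, d]`.
#'
#' @param F frames x muscles force matrix, N.
#' @param r frames x muscles x DOFs moment-arm array, m.
#' @return frames x DOFs moment matrix, N*m.
#' @export
net_joint_moments <- function(F, r) {
  if (!all(dim(F) == dim(r)[1:2])) stop("shape mismatch between F and r")
  nd <- dim(r)[3]
  M <- matrix(0, nrow(F), nd, dimnames = list(NULL, dimnames(r)[[3]]))
  for (d in seq_len(nd)) M[, d] <- rowSums(F * r[, , d, drop = TRUE])
  M
}

#' Muscle-tendon parameter table
#'
#' One row per muscle with the activation-dynamics and Hill-model
#' parameters. `lo_nom` and `ls_nom` are nominal optimal fiber and tendon
#' slack lengths; the calibration adjusts the dimensionless `scale_lo` and
#' `scale_ls` factors (bounds `[0.6, 1.4]`), so the effective lengths are
#' `scale_lo * lo_nom` and `scale_ls * ls_nom`.
#'
#' @param muscles character vector of muscle names.
#' @param semg EMG scale factor(s) in `[0.05, 1]`.
#' @param d electromechanical delay(s), s, in `[0, 0.1]`.
#' @param tau_act activation time constant(s), s.
#' @param c3 activation nonlinearity constant(s) in `[0, 1)`.
#' @param fmax maximum isometric force(s), N.
#' @param lo_nom nominal optimal fiber length(s), m.
#' @param ls_nom nominal tendon slack length(s), m.
#' @param alpha pennation angle(s), rad.
#' @param scale_lo,scale_ls length scale factor(s) in `[0.6, 1.4]`.
#' @return data.frame of class `muscle_params`, row names = muscle names.
#' @export
muscle_params <- function(muscles, semg = 0.9, d = 0.03, tau_act = 0.02,
                          c3 = 0.1, fmax = 1000, lo_nom = 0.1,
                          ls_nom = 0.2, alpha = 0, scale_lo = 1,
                          scale_ls = 1) {
  n <- length(muscles)
  out <- data.frame(semg = rep_len(semg, n), d = rep_len(d, n),
                    tau_act = rep_len(tau_act, n), c3 = rep_len(c3, n),
                    fmax = rep_len(fmax, n), lo_nom = rep_len(lo_nom, n),
                    ls_nom = rep_len(ls_nom, n), alpha = rep_len(alpha, n),
                    scale_lo = rep_len(scale_lo, n),
                    scale_ls = rep_len(scale_ls, n),
                    row.names = muscles)
  if (any(out$semg < 0.05 - 1e-9) || any(out$semg > 1 + 1e-9))
    stop("semg must lie in [0.05, 1]")
  if (any(out$d < 0) || any(out$d > 0.1 + 1e-9))
    stop("delay must lie in [0, 0.1] s")
  if (any(out$scale_lo < 0.6 - 1e-9) || any(out$scale_lo > 1.4 + 1e-9) ||
      any(out$scale_ls < 0.6 - 1e-9) || any(out$scale_ls > 1.4 + 1e-9))
    stop("length scale factors must lie in [0.6, 1.4]")
  class(out) <- c("muscle_params", "data.frame")
  out
}

# Kinematic quantities of one trial that do not depend on the calibrated
# parameters: muscle-tendon lengths/velocities and moment arms.
.trial_kinematics <- function(trial, geometry) {
  list(lmt = muscle_tendon_lengths(geometry, trial$joint_angles),
       vmt = muscle_tendon_velocities(geometry, trial$joint_angles,
                                      trial$joint_velocities),
       r = moment_arms(geometry, trial$joint_angles),
       dt = trial$cycle_duration / (trial$n_cycle - 1))
}

# Forward chain from precomputed kinematics; exc is the full frames x
# muscles excitation matrix (all model muscles, in params row order).
# The default curve family runs through the compiled kernel; custom curve
# registries take the equivalent R path.
.forward_from_kinematics <- function(exc, params, kin, n_pre,
                                     curves = default_muscle_curves(),
                                     g = default_g_constants()) {
  if (isTRUE(attr(curves, "native"))) {
    if (max(params$d) > n_pre * kin$dt + 1e-12)
      stop("delay exceeds the pre-frame buffer")
    cc <- compute_c_constants(params$tau_act)
    out <- .forward_chain_cpp(exc, params$semg, params$d, cc$c1, cc$c2,
                              params$c3, unname(g), kin$lmt, kin$vmt,
                              kin$r, params$scale_lo * params$lo_nom,
                              params$scale_ls * params$ls_nom,
                              params$fmax, cos(params$alpha), kin$dt,
                              attr(curves, "fl_gamma") %||% 0.45)
    mus <- colnames(exc)
    dimnames(out$u) <- dimnames(out$a) <- dimnames(out$F) <-
      list(NULL, mus)
    colnames(out$M) <- dimnames(kin$r)[[3]]
    return(out)
  }
  e <- sweep(exc, 2L, params$semg, "*")
  e[e < 0] <- 0
  e[e > 1] <- 1
  u <- activation_dynamics(e, params$tau_act, params$d, kin$dt, n_pre)
  a <- activation_nonlinearity(u, params$c3, g)
  lo <- params$scale_lo * params$lo_nom
  ls <- params$scale_ls * params$ls_nom
  fib <- normalized_fiber_kinematics(kin$lmt, kin$vmt, lo, ls)
  F <- muscle_force(a, fib$l, fib$v, params$fmax, params$alpha, curves)
  M <- net_joint_moments(F, kin$r)
  list(u = u, a = a, F = F, M = M)
}

#' Run the EMG-driven forward chain for one trial
#'
#' Scales excitations by `semg`, clamps to `[0, 1]`, applies delayed
#' activation dynamics and the activation nonlinearity, evaluates
#' rigid-tendon Hill-type forces, and sums moment-arm-weighted forces into
#' net joint moments. All outputs are on the full 121-frame grid; use
#' [cycle_frames()] to slice the 101 cycle frames.
#'
#' @param trial a [gait_trial()] providing angles, velocities and the time
#'   grid.
#' @param params a [muscle_params()] table covering every column of
#'   `excitations`.
#' @param geometry a geometry object spanning the model's muscles/DOFs.
#' @param excitations frames x muscles matrix; defaults to the trial's own
#'   excitations. Columns must match `rownames(params)`.
#' @param curves Hill curve set (default [default_muscle_curves()]).
#' @param g activation-nonlinearity constants.
#' @return list with matrices `u`, `a` (activations), `F` (forces, N) and
#'   `M` (net joint moments, N*m), all frames x (muscles | DOFs).
#' @export
forward_chain <- function(trial, params, geometry, excitations = NULL,
                          curves = default_muscle_curves(),
                          g = default_g_constants()) {
  if (is.null(excitations)) excitations <- trial$excitations
  excitations <- as.matrix(excitations)[, rownames(params), drop = FALSE]
  kin <- .trial_kinematics(trial, geometry)
  .forward_from_kinematics(excitations, params, kin, trial$n_pre, curves, g)
}
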