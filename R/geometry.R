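# Musculoskeletal geometry: muscle-tendon length as a function of joint
# angles, with moment arms r = -d(lMT)/d(theta) and velocities
# vMT = sum_d (d lMT/d theta_d) * thetadot_d = -sum_d r_d * thetadot_d.
# Two implementations share one interface: an analytic sinusoidal fixture
# (planar_leg_fixture) and a fitted polynomial surrogate (fit_surrogate).

#' Muscle-tendon lengths for all muscles at given joint angles
#' @param geometry a geometry object (`planar_geometry` or
#'   `surrogate_geometry`).
#' @param theta frames x DOFs matrix of joint angles, radians, with DOF
#'   column names.
#' @return frames x muscles matrix, metres.
#' @export
muscle_tendon_lengths <- function(geometry, theta)
  UseMethod("muscle_tendon_lengths")

#' Moment arms for all muscles and DOFs at given joint angles
#'
#' The moment arm is the negative partial derivative of muscle-tendon
#' length with respect to the generalised coordinate; it is identically 0
#' for DOFs a muscle does not span.
#'
#' @inheritParams muscle_tendon_lengths
#' @return frames x muscles x DOFs array, metres.
#' @export
moment_arms <- function(geometry, theta) UseMethod("moment_arms")

#' Muscle-tendon velocities from moment arms and joint velocities
#'
#' Chain rule: `vMT = -sum_d r_d * thetadot_d`.
#'
#' @param geometry a geometry object.
#' @param theta frames x DOFs joint angles, radians.
#' @param thetadot frames x DOFs joint velocities, rad/s.
#' @return frames x muscles matrix, m/s.
#' @export
muscle_tendon_velocities <- function(geometry, theta, thetadot) {
  r <- moment_arms(geometry, theta)
  thetadot <- as.matrix(thetadot)
  v <- matrix(0, nrow(thetadot), dim(r)[2],
              dimnames = list(NULL, dimnames(r)[[2]]))
  for (d in seq_len(dim(r)[3]))
    v <- v - r[, , d] * thetadot[, d]
  v
}

#' Moment arm of one muscle about one DOF
#' @param geometry a geometry object.
#' @param theta numeric vector (one frame) or matrix of joint angles with
#'   DOF names.
#' @param muscle muscle name.
#' @param dof DOF name.
#' @return moment arm(s) in metres (0 for a non-spanned DOF).
#' @export
moment_arm <- function(geometry, theta, muscle, dof) {
  if (is.null(dim(theta)))
    theta <- matrix(theta, 1, dimnames = list(NULL, names(theta)))
  r <- moment_arms(geometry, theta)
  r[, muscle, dof]
}

#' Analytic planar-leg geometry
#'
#' Sinusoidal muscle paths `lMT(theta) = l0 - sum_i rho_i *
#' sin(theta_i + phi_i)` over each muscle's spanned DOFs, giving analytic
#' moment arms `r_i = rho_i * cos(theta_i + phi_i)`. A positive `rho`
#' produces a muscle that shortens as the joint angle increases (a
#' "flexor-like" path); antagonists use opposite signs.
#'
#' @param muscles named list; each element has `l0` (m), and named numeric
#'   vectors `rho` (m) and `phi` (rad) keyed by spanned DOF name.
#' @param dof_names character vector of all DOF names.
#' @return object of class `planar_geometry`.
#' @export
planar_geometry <- function(muscles, dof_names) {
  for (nm in names(muscles)) {
    m <- muscles[[nm]]
    if (!all(names(m$rho) %in% dof_names))
      stop("muscle ", nm, " spans unknown DOF(s)")
    if (!identical(names(m$rho), names(m$phi)))
      stop("rho and phi of muscle ", nm, " must share DOF names")
  }
  structure(list(muscles = muscles, dof_names = dof_names),
            class = "planar_geometry")
}

#' @export
muscle_tendon_lengths.planar_geometry <- function(geometry, theta) {
  theta <- as.matrix(theta)
  out <- matrix(0, nrow(theta), length(geometry$muscles),
                dimnames = list(NULL, names(geometry$muscles)))
  for (nm in names(geometry$muscles)) {
    m <- geometry$muscles[[nm]]
    l <- rep(m$l0, nrow(theta))
    for (d in names(m$rho))
      l <- l - m$rho[[d]] * sin(theta[, d] + m$phi[[d]])
    out[, nm] <- l
  }
  out
}

#' @export
moment_arms.planar_geometry <- function(geometry, theta) {
  theta <- as.matrix(theta)
  mus <- names(geometry$muscles)
  r <- array(0, c(nrow(theta), length(mus), length(geometry$dof_names)),
             dimnames = list(NULL, mus, geometry$dof_names))
  for (nm in mus) {
    m <- geometry$muscles[[nm]]
    for (d in names(m$rho))
      r[, nm, d] <- m$rho[[d]] * cos(theta[, d] + m$phi[[d]])
  }
  r
}

# All exponent tuples over nv variables with total degree 1..degree.
.poly_exponents <- function(nv, degree) {
  grids <- do.call(expand.grid, rep(list(0:degree), nv))
  grids <- as.matrix(grids[rowSums(grids) <= degree & rowSums(grids) > 0, ,
                           drop = FALSE])
  dimnames(grids) <- NULL
  grids
}

.poly_design <- function(theta, expo) {
  X <- matrix(1, nrow(theta), nrow(expo))
  for (j in seq_len(ncol(expo))) {
    nz <- expo[, j] > 0
    if (any(nz))
      X[, nz] <- X[, nz, drop = FALSE] *
        outer(theta[, j], expo[nz, j], "^")
  }
  X
}

#' Fit a polynomial surrogate geometry to sampled muscle-tendon lengths
#'
#' Least-squares fit of a multivariate polynomial (total degree <=
#' `degree`) of `lMT` over each muscle's spanned joint angles. Moment arms
#' and muscle-tendon velocities are obtained analytically from the fitted
#' polynomial (never fitted independently).
#'
#' @param samples named list per muscle: `theta` (n x spanned-DOFs matrix of
#'   joint angles with DOF column names) and `lmt` (length-n vector of
#'   muscle-tendon lengths, metres).
#' @param dof_names character vector of all DOF names in the model.
#' @param degree polynomial total degree (default 4).
#' @return object of class `surrogate_geometry`; element `max_residual`
#'   records the worst absolute fit residual per muscle.
#' @export
fit_surrogate <- function(samples, dof_names, degree = 4L) {
  fits <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    th <- as.matrix(s$theta)
    spanned <- colnames(th)
    if (is.null(spanned) || !all(spanned %in% dof_names))
      stop("theta samples for ", nm, " must name spanned DOFs")
    expo <- .poly_exponents(ncol(th), degree)
    X <- cbind(1, .poly_design(th, expo))
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient design for muscle ", nm,
           ": sample more angle combinations or lower the degree")
    coefs <- qr.coef(qrX, s$lmt)
    fits[[nm]] <- list(spanned = spanned, expo = expo,
                       intercept = coefs[1], coef = coefs[-1],
                       max_residual = max(abs(s$lmt - X %*% coefs)))
  }
  structure(list(muscles = fits, dof_names = dof_names,
                 degree = as.integer(degree),
                 max_residual = vapply(fits, `[[`, numeric(1),
                                       "max_residual")),
            class = "surrogate_geometry")
}

#' @export
muscle_tendon_lengths.surrogate_geometry <- function(geometry, theta) {
  theta <- as.matrix(theta)
  out <- matrix(0, nrow(theta), length(geometry$muscles),
                dimnames = list(NULL, names(geometry$muscles)))
  for (nm in names(geometry$muscles)) {
    f <- geometry$muscles[[nm]]
    X <- .poly_design(theta[, f$spanned, drop = FALSE], f$expo)
    out[, nm] <- f$intercept + X %*% f$coef
  }
  out
}

#' @export
moment_arms.surrogate_geometry <- function(geometry, theta) {
  theta <- as.matrix(theta)
  mus <- names(geometry$muscles)
  r <- array(0, c(nrow(theta), length(mus), length(geometry$dof_names)),
             dimnames = list(NULL, mus, geometry$dof_names))
  for (nm in mus) {
    f <- geometry$muscles[[nm]]
    th <- theta[, f$spanned, drop = FALSE]
    for (j in seq_along(f$spanned)) {
      dexpo <- f$expo
      keep <- dexpo[, j] > 0
      if (!any(keep)) next
      dcoef <- f$coef[keep] * dexpo[keep, j]
      dexpo <- dexpo[keep, , drop = FALSE]
      dexpo[, j] <- dexpo[, j] - 1L
      X <- .poly_design(th, dexpo)
      # r = -d(lMT)/d(theta)
      r[, nm, f$spanned[j]] <- -(X %*% dcoef)
    }
  }
  r
}

#' Sample a geometry over an angle grid for surrogate fitting
#'
#' Builds the `samples` input of [fit_surrogate()] by evaluating another
#' geometry (typically the analytic fixture) on a regular grid over each
#' muscle's spanned DOFs.
#'
#' @param geometry a geometry object with known spanned DOFs per muscle.
#' @param ranges named list of `c(min, max)` angle ranges, radians, per DOF.
#' @param n_per_dof grid points per spanned DOF (default 9).
#' @return named list suitable as `samples` for [fit_surrogate()].
#' @export
sample_geometry <- function(geometry, ranges, n_per_dof = 9L) {
  stopifnot(inherits(geometry, "planar_geometry"))
  out <- list()
  for (nm in names(geometry$muscles)) {
    spanned <- names(geometry$muscles[[nm]]$rho)
    axes <- lapply(spanned, function(d)
      seq(ranges[[d]][1], ranges[[d]][2], length.out = n_per_dof))
    grid <- as.matrix(do.call(expand.grid, axes))
    colnames(grid) <- spanned
    # embed into full-DOF angle matrix (non-spanned angles are irrelevant)
    full <- matrix(0, nrow(grid), length(geometry$dof_names),
                   dimnames = list(NULL, geometry$dof_names))
    full[, spanned] <- grid
    out[[nm]] <- list(theta = grid,
                      lmt = muscle_tendon_lengths(geometry, full)[, nm])
  }
  out
}
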