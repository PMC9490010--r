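# S3 methods for synx_fit objects.

#' @export
print.synx_fit <- function(x, ...) {
  cat("EMG-driven model calibration (", x$case, ")\n", sep = "")
  cat("  trials: ", length(x$problem$trials),
      " | design variables: ", x$problem$n_design,
      " | converged: ", x$convergence, "\n", sep = "")
  cat("  cost J = ", format(x$cost, digits = 6), "  [",
      paste(sprintf("%s=%.4g", names(x$terms), x$terms), collapse = ", "),
      "]\n", sep = "")
  mm <- moment_tracking(x)
  cat("  moment tracking MAE (N*m):",
      paste(sprintf("%s=%.3f", names(mm$mae_per_dof), mm$mae_per_dof),
            collapse = ", "), "\n")
  invisible(x)
}

#' Calibrated parameters of a fit
#'
#' @param object a `synx_fit`.
#' @param ... unused.
#' @return the calibrated [muscle_params()] table.
#' @export
coef.synx_fit <- function(object, ...) object$params

#' Model-predicted joint moments of the calibration trials
#'
#' @param object a `synx_fit`.
#' @param include_residuals return `Mpreres` instead of `Mpre` where
#'   residual excitations were calibrated; defaults to the fit's cost
#'   configuration flag.
#' @param ... unused.
#' @return named list of 101-frame x DOFs matrices, one per trial.
#' @export
fitted.synx_fit <- function(object,
                            include_residuals =
                              object$problem$cost$include_residual_in_reported_moments,
                            ...) {
  lapply(object$outputs, function(o)
    if (include_residuals && !is.null(o$Mpreres)) o$Mpreres else o$Mpre)
}

#' Joint-moment tracking residuals (model minus inverse dynamics)
#' @inheritParams fitted.synx_fit
#' @return named list of 101-frame x DOFs matrices.
#' @export
residuals.synx_fit <- function(object,
                               include_residuals =
                                 object$problem$cost$include_residual_in_reported_moments,
                               ...) {
  M <- fitted(object, include_residuals = include_residuals)
  lapply(names(M), function(id) M[[id]] - object$outputs[[id]]$Mexp) |>
    stats::setNames(names(M))
}

#' Moment-tracking summary of a fit
#'
#' @param fit a `synx_fit`.
#' @param include_residuals see [fitted.synx_fit()].
#' @return list with `mae_per_dof`, `rmse_per_dof` (N*m, averaged over
#'   trials) and the overall `mae`.
#' @export
moment_tracking <- function(fit,
                            include_residuals =
                              fit$problem$cost$include_residual_in_reported_moments) {
  res <- residuals(fit, include_residuals = include_residuals)
  R <- do.call(rbind, res)
  list(mae_per_dof = apply(abs(R), 2L, mean),
       rmse_per_dof = sqrt(apply(R^2, 2L, mean)),
       mae = mean(abs(R)))
}

#' Estimated unmeasured muscle excitations of the calibration trials
#' @param fit a `synx_fit` of a SynX case.
#' @return named list of 121-frame x unmeasured matrices.
#' @export
synx_excitations <- function(fit) {
  if (!fit$problem$use_synx)
    stop("fit has no SynX component (case ", fit$case, ")")
  lapply(fit$outputs, `[[`, "eSynX")
}

#' @export
summary.synx_fit <- function(object, ...) {
  mm <- moment_tracking(object)
  out <- list(case = object$case, cost = object$cost, terms = object$terms,
              convergence = object$convergence,
              counts = object$optim$counts,
              mae_per_dof = mm$mae_per_dof,
              rmse_per_dof = mm$rmse_per_dof,
              params = object$params)
  class(out) <- "summary.synx_fit"
  out
}

#' @export
print.summary.synx_fit <- function(x, ...) {
  cat("Calibration case:", x$case, "\n")
  cat("Converged:", x$convergence, " (",
      paste(names(x$counts), x$counts, collapse = ", "), ")\n")
  cat("Cost:", format(x$cost, digits = 6), "\n")
  for (nm in names(x$terms))
    if (x$terms[[nm]] > 0)
      cat("  ", nm, "=", format(x$terms[[nm]], digits = 6), "\n")
  cat("Joint-moment tracking (per DOF):\n")
  print(round(rbind(MAE = x$mae_per_dof, RMSE = x$rmse_per_dof), 4))
  cat("Calibrated parameters:\n")
  print(round(as.data.frame(x$params), 4))
  invisible(x)
}

#' Validate a calibrated model on new trials
#'
#' Applies the fitted model parameters and the *fixed* calibrated
#' unmeasured synergy weights to trials not used in calibration: measured
#' synergy excitations for the new trials are obtained by projecting the
#' new measured excitations onto the calibration decomposition's synergy
#' basis (loadings and channel means of the trial's group under the
#' calibrated category), so the weights stay attached to the components
#' they were calibrated against -- a freshly run PCA would carry
#' arbitrary component signs and, for close variances, rotations. The
#' projected synergy excitations are combined with the calibrated
#' `H`/`mu` and pushed through the forward chain. Only speed- or
#' subject-specific weights can transfer to new trials; trial-specific
#' fits are rejected.
#'
#' @param object a `synx_fit` of a SynX case with speed- or
#'   subject-specific unmeasured weights.
#' @param newdata a [gait_dataset()] with the same muscles/DOFs and speed
#'   labels covered by the calibrated weight sets.
#' @param ... unused.
#' @return object of class `synx_validation`: per-trial `eSynX`, predicted
#'   moments `M`, activations `a`, and a per-trial/DOF `metrics`
#'   data.frame (MAE, RMSE, r) against the new trials' ID moments.
#' @export
predict.synx_fit <- function(object, newdata, ...) {
  if (!object$problem$use_synx)
    stop("predict() requires a SynX case fit")
  cat_unm <- object$problem$layout$category_unmeasured
  if (cat_unm == "trial")
    stop("trial-specific unmeasured weights cannot transfer to new trials;",
         " calibrate with speed- or subject-specific weights")
  stopifnot(inherits(newdata, "gait_dataset"))
  w <- object$weights$unmeasured
  decs <- object$problem$decs_unm
  unm <- object$problem$unmeasured
  params <- object$params
  if (!identical(newdata$measured_muscles,
                 object$problem$measured))
    stop("newdata must share the fit's measured-muscle set")
  out <- list(); metr <- list()
  for (id in names(newdata$trials)) {
    tr <- newdata$trials[[id]]
    g <- .group_of_trial(newdata, id, cat_unm)
    if (is.null(w$H[[g]]))
      stop("no calibrated weight set for group ", g)
    dec <- decs[[g]]
    E_new <- tr$excitations[, newdata$measured_muscles, drop = FALSE]
    Ec <- sweep(E_new, 2L, as.numeric(dec$mu))
    Wm_new <- Ec %*% t(dec$Hm)          # loadings are orthonormal rows
    sd_ <- dec$sdev[seq_len(ncol(Wm_new))]
    Wm_new <- sweep(Wm_new, 2L, pmax(sd_, 1e-6 * sd_[1]), "/")
    eS <- construct_unmeasured(Wm_new, w$H[[g]], w$mu[[g]])
    colnames(eS) <- unm
    E <- matrix(0, length(tr$time), length(object$problem$model_muscles),
                dimnames = list(NULL, object$problem$model_muscles))
    E[, newdata$measured_muscles] <-
      tr$excitations[, newdata$measured_muscles]
    E[, unm] <- eS
    fwd <- forward_chain(tr, params, object$problem$geometry,
                         excitations = E)
    cyc <- cycle_frames(tr)
    M <- fwd$M[cyc, , drop = FALSE]
    Mexp <- tr$id_moments[cyc, , drop = FALSE]
    out[[id]] <- list(eSynX = eS, M = M, a = fwd$a)
    metr[[id]] <- do.call(rbind, lapply(colnames(M), function(d)
      data.frame(trial = id, dof = d,
                 mae = mae(M[, d], Mexp[, d]),
                 rmse = rmse(M[, d], Mexp[, d]),
                 r = stats::cor(M[, d], Mexp[, d]))))
  }
  structure(list(trials = out,
                 metrics = do.call(rbind, metr),
                 category = cat_unm),
            class = "synx_validation")
}

#' @export
print.synx_validation <- function(x, ...) {
  cat("<synx_validation> ", length(x$trials), " trials (",
      x$category, "-specific weights)\n", sep = "")
  agg <- stats::aggregate(cbind(mae, rmse, r) ~ dof, x$metrics, mean)
  print(round(agg[, -1], 4) |> (\(d) {rownames(d) <- agg$dof; d})())
  invisible(x)
}

#' Plot joint-moment tracking of a fit
#'
#' One panel per DOF: inverse-dynamics moments (grey) and model-predicted
#' moments (coloured) over percent gait cycle, all trials overlaid.
#'
#' @param x a `synx_fit`.
#' @param dofs DOF names to plot (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.synx_fit <- function(x, dofs = NULL, ...) {
  M <- fitted(x)
  dofs <- dofs %||% colnames(M[[1]])
  pct <- seq(0, 100, length.out = nrow(M[[1]]))
  old <- graphics::par(mfrow = c(length(dofs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in dofs) {
    exp_ <- sapply(x$outputs, function(o) o$Mexp[, d])
    mod_ <- sapply(M, function(m) m[, d])
    graphics::matplot(pct, exp_, type = "l", lty = 1,
                      col = grDevices::grey(0.75),
                      xlab = "% gait cycle", ylab = "moment (N*m)",
                      main = d, ...)
    graphics::matlines(pct, mod_, lty = 1, col = "steelblue")
  }
  invisible(x)
}
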