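# Calibration of the EMG-driven model with simultaneous synergy
# extrapolation: a bound-constrained nonlinear least-squares-type problem
# over activation-dynamics parameters, muscle-tendon length scale factors,
# and SynX/residual synergy vector weights, scored by joint-moment
# tracking with magnitude regularisation of the estimated activations.

#' Cost configuration: maximum allowable deviations (MADs)
#'
#' The terms are: moment tracking with residuals (`mad_mom_res`, N*m),
#' moment tracking without residuals (`mad_mom`, N*m), unmeasured
#' activation magnitude (`mad_act_synx`, activation units) and residual
#' activation magnitude (`mad_act_res`, activation units).
#'
#' The four cost terms are sums of squares normalised by a maximum
#' allowable deviation each; the defaults come from the package's own
#' sensitivity analysis (see the methods vignette): 0.5 N*m for the moment
#' terms and 1.0 activation units for the magnitude terms. The ratio is
#' what matters: it makes moment tracking dominate so the activation
#' regularisers act as weak priors that curb overestimation and resolve
#' redundancy without biasing the tracked solution, while still being
#' strong enough to guide the optimizer away from spurious basins.
#'
#' An auxiliary penalty (`Jpen`, scale `mad_exc_penalty`) pushes
#' constructed excitations that leave the physical `[0, 1]` range back in:
#' the muscle model clamps its excitation input, so out-of-range values
#' are otherwise invisible to the cost and can trap the optimizer on a
#' flat region. The penalty is exactly zero whenever constructed
#' excitations stay in range, so it does not bias a feasible optimum; set
#' `mad_exc_penalty = Inf` to disable it.
#'
#' @param mad_mom_res,mad_mom,mad_act_synx,mad_act_res positive scales.
#' @param mad_exc_penalty scale of the out-of-range excitation penalty
#'   (excitation units; default 0.1).
#' @param include_residual_in_reported_moments if `TRUE` (default) the
#'   fit's reported tracking moments are `Mpreres` where residuals exist.
#' @return list of class `cost_config`.
#' @export
cost_config <- function(mad_mom_res = 0.5, mad_mom = 0.5,
                        mad_act_synx = 1, mad_act_res = 1,
                        mad_exc_penalty = 0.1,
                        include_residual_in_reported_moments = TRUE) {
  mads <- c(mad_mom_res, mad_mom, mad_act_synx, mad_act_res,
            mad_exc_penalty)
  if (any(mads <= 0)) stop("all MADs must be positive")
  structure(list(mad_mom_res = mad_mom_res, mad_mom = mad_mom,
                 mad_act_synx = mad_act_synx, mad_act_res = mad_act_res,
                 mad_exc_penalty = mad_exc_penalty,
                 include_residual_in_reported_moments =
                   include_residual_in_reported_moments),
            class = "cost_config")
}

# Out-of-range part of constructed excitations, in penalty units.
.range_excess <- function(E, scale) {
  if (!is.finite(scale)) return(numeric(0))
  as.numeric(cbind(pmin(E, 0), pmax(E - 1, 0)) / scale)
}

#' Design-variable bounds
#'
#' Box bounds for the calibrated quantities: EMG scale `semg` in
#' `[0.05, 1]`, electromechanical delay `d` in `[0, 0.1]` s, activation
#' time constant in `[0.01, 0.05]` s, nonlinearity constant `c3` in
#' `[0, 0.35]`, fiber/tendon length scale factors in `[0.6, 1.4]`, synergy
#' weight entries in `[-5, 5]` and average values in `[-1, 2]`.
#'
#' @param semg,d,tau_act,c3,scale,H,mu length-2 numeric ranges.
#' @return list of class `synx_bounds`.
#' @export
synx_bounds <- function(semg = c(0.05, 1), d = c(0, 0.1),
                        tau_act = c(0.01, 0.05), c3 = c(0, 0.35),
                        scale = c(0.6, 1.4), H = c(-5, 5),
                        mu = c(-1, 2)) {
  structure(list(semg = semg, d = d, tau_act = tau_act, c3 = c3,
                 scale = scale, H = H, mu = mu),
            class = "synx_bounds")
}

.param_fields <- c("semg", "d", "tau_act", "c3", "scale_lo", "scale_ls")

#' Build a calibration problem
#'
#' Assembles everything a cost evaluation needs: the per-trial kinematic
#' caches, the synergy decompositions for the categories in play, the flat
#' design-vector layout, and its bounds. Three cases are supported:
#' * `"params_synx_res"` -- model parameters + unmeasured weights +
#'   residual weights (four cost terms);
#' * `"params_synx"` -- model parameters + unmeasured weights, residual
#'   excitations identically zero (two cost terms);
#' * `"params"` -- model parameters only, the full experimental excitation
#'   set is used (one cost term).
#'
#' @param dataset a [gait_dataset()]; for the SynX cases its unmeasured
#'   set must be non-empty.
#' @param geometry geometry covering all model muscles.
#' @param params nominal [muscle_params()] table (provides `fmax`,
#'   `lo_nom`, `ls_nom`, `alpha`, and the frozen values when
#'   `fix_params = TRUE`).
#' @param case calibration case.
#' @param n_synergies number of synergies `p` for the SynX cases.
#' @param category_unmeasured,category_residual weight categories
#'   (`"trial"`, `"speed"`, `"subject"`); each side uses the synergy
#'   decomposition of its own category.
#' @param cost a [cost_config()].
#' @param bounds a [synx_bounds()].
#' @param fix_params if `TRUE`, the activation-dynamics and scale
#'   parameters are frozen at the values in `params` and only weights are
#'   design variables.
#' @param curves,g Hill curve set and nonlinearity constants.
#' @return object of class `synx_problem`.
#' @export
synx_problem <- function(dataset, geometry, params,
                         case = c("params_synx_res", "params_synx",
                                  "params"),
                         n_synergies = 6L,
                         category_unmeasured = "trial",
                         category_residual = "trial",
                         cost = cost_config(), bounds = synx_bounds(),
                         fix_params = FALSE,
                         curves = default_muscle_curves(),
                         g = default_g_constants()) {
  case <- match.arg(case)
  stopifnot(inherits(dataset, "gait_dataset"),
            inherits(params, "muscle_params"))
  model_muscles <- rownames(params)
  if (!all(muscle_names(dataset) %in% model_muscles))
    stop("params must cover every muscle in the dataset")
  measured <- dataset$measured_muscles
  unmeasured <- dataset$unmeasured_muscles
  use_synx <- case %in% c("params_synx", "params_synx_res")
  use_res <- case == "params_synx_res"
  if (use_synx && length(unmeasured) == 0)
    stop("case ", case, " requires a non-empty unmeasured muscle set")
  if (case == "params") unmeasured <- character()

  decs_unm <- decs_res <- NULL
  if (use_synx)
    decs_unm <- decompose_dataset(dataset, n_synergies, category_unmeasured)
  if (use_res)
    decs_res <- if (category_residual == category_unmeasured) decs_unm
      else decompose_dataset(dataset, n_synergies, category_residual)

  ids <- names(dataset$trials)
  groups_unm <- if (use_synx)
    unique(vapply(ids, .group_of_trial, character(1), dataset = dataset,
                  category = category_unmeasured)) else character()
  groups_res <- if (use_res)
    unique(vapply(ids, .group_of_trial, character(1), dataset = dataset,
                  category = category_residual)) else character()
  layout <- weight_layout(n_synergies,
                          if (use_synx) length(unmeasured) else 0L,
                          if (use_res) length(measured) else 0L,
                          groups_unm, groups_res,
                          category_unmeasured, category_residual)

  # per-trial caches: kinematics, target moments, base excitations, Wm
  trials <- lapply(ids, function(id) {
    tr <- dataset$trials[[id]]
    kin <- .trial_kinematics(tr, geometry)
    E_base <- matrix(0, length(tr$time), length(model_muscles),
                     dimnames = list(NULL, model_muscles))
    if (case == "params") {
      E_base[, muscle_names(dataset)] <- tr$excitations
    } else {
      E_base[, measured] <- tr$excitations[, measured]
    }
    list(id = id, kin = kin, E_base = E_base,
         Mexp = tr$id_moments[cycle_frames(tr), , drop = FALSE],
         n_pre = tr$n_pre, cycle = cycle_frames(tr),
         wm_unm = if (use_synx)
           .wm_for_trial(decs_unm, id, normalize = TRUE)$Wm,
         wm_res = if (use_res)
           .wm_for_trial(decs_res, id, normalize = TRUE)$Wm,
         group_unm = if (use_synx)
           .group_of_trial(dataset, id, category_unmeasured),
         group_res = if (use_res)
           .group_of_trial(dataset, id, category_residual))
  })
  names(trials) <- ids

  n_par <- if (fix_params) 0L else 6L * length(model_muscles)
  # mean measured excitation level: initial guess for mu_synx
  mu_meas <- mean(vapply(ids, function(id)
    mean(measured_excitations(dataset, id)), numeric(1)))

  structure(list(case = case, dataset = dataset, geometry = geometry,
                 params = params, model_muscles = model_muscles,
                 measured = measured, unmeasured = unmeasured,
                 use_synx = use_synx, use_res = use_res,
                 n_synergies = as.integer(n_synergies),
                 decs_unm = decs_unm, decs_res = decs_res,
                 layout = layout, cost = cost, bounds = bounds,
                 fix_params = fix_params, n_par = n_par,
                 n_design = as.integer(n_par + layout$length),
                 trials = trials, mu_meas_mean = mu_meas,
                 curves = curves, g = g),
            class = "synx_problem")
}

#' @export
print.synx_problem <- function(x, ...) {
  cat("<synx_problem> case:", x$case, "\n")
  cat("  trials:", length(x$trials), "| muscles:", length(x$model_muscles),
      "(", length(x$unmeasured), "unmeasured ) | design variables:",
      x$n_design, "\n")
  if (x$use_synx)
    cat("  synergies:", x$n_synergies, "| categories:",
        x$layout$category_unmeasured, "(unmeasured)",
        if (x$use_res) paste0("/ ", x$layout$category_residual,
                              " (residual)"), "\n")
  invisible(x)
}

# Natural-unit bounds of the full design vector, in layout order.
.design_bounds <- function(problem) {
  b <- problem$bounds
  lb <- ub <- numeric(0)
  if (!problem$fix_params) {
    nm <- length(problem$model_muscles)
    for (field in .param_fields) {
      rng <- switch(field, semg = b$semg, d = b$d, tau_act = b$tau_act,
                    c3 = b$c3, scale_lo = , scale_ls = b$scale)
      lb <- c(lb, rep(rng[1], nm)); ub <- c(ub, rep(rng[2], nm))
    }
  }
  lay <- problem$layout
  side <- function(q, groups) {
    per_h <- lay$p * q
    unlist(lapply(groups, function(g)
      c(rep(1, per_h), rep(2, q))))  # 1 = H entry, 2 = mu entry
  }
  kinds <- c(side(lay$q_unmeasured, lay$groups_unmeasured),
             side(lay$q_measured, lay$groups_residual))
  if (length(kinds)) {
    lb <- c(lb, ifelse(kinds == 1, b$H[1], b$mu[1]))
    ub <- c(ub, ifelse(kinds == 1, b$H[2], b$mu[2]))
  }
  list(lb = lb, ub = ub)
}

# Split a natural-unit design vector into a params table and weight sets.
.unpack_design <- function(problem, x) {
  params <- problem$params
  if (!problem$fix_params) {
    nm <- length(problem$model_muscles)
    for (i in seq_along(.param_fields))
      params[[.param_fields[i]]] <- x[(i - 1L) * nm + seq_len(nm)]
  }
  weights <- unpack_weights(problem$layout,
                            x[problem$n_par + seq_len(problem$layout$length)])
  list(params = params, weights = weights)
}

#' Evaluate the calibration cost
#'
#' Computes the total cost and its terms at a natural-unit design vector:
#' `J = JMomres + JMom + JactSynX + Jactres` for the full case, dropping
#' the terms a case excludes. Sums run over the 101 cycle frames, all
#' DOFs/muscles and all trials. Non-finite model outputs yield a non-finite
#' cost (reported, not an error), which the optimizer treats as a rejected
#' step.
#'
#' @param problem a [synx_problem()].
#' @param x design vector of length `problem$n_design` (parameter block
#'   first, then weights; see [weight_layout()]).
#' @param details if `TRUE`, also return per-trial model outputs.
#' @return list with `J` and `terms` (and `outputs` when `details`).
#' @export
evaluate_cost <- function(problem, x, details = FALSE) {
  des <- .unpack_design(problem, x)
  terms <- c(JMomres = 0, JMom = 0, JactSynX = 0, Jactres = 0, Jpen = 0)
  outputs <- if (details) list()
  for (tc in problem$trials) {
    one <- .trial_cost(problem, tc, des$params, des$weights,
                       details = details)
    terms <- terms + one$terms
    if (details) outputs[[tc$id]] <- one$output
  }
  keep <- .cost_terms_of_case(problem$case)
  terms[setdiff(names(terms), keep)] <- 0
  out <- list(J = sum(terms[keep]), terms = terms)
  if (details) out$outputs <- outputs
  out
}

.cost_terms_of_case <- function(case) {
  switch(case,
         params = "JMom",
         params_synx = c("JMom", "JactSynX", "Jpen"),
         params_synx_res = c("JMomres", "JMom", "JactSynX", "Jactres",
                             "Jpen"))
}

# Cost contribution of one trial (all four terms, unmasked).
.trial_cost <- function(problem, tc, params, w, details = FALSE) {
  cfg <- problem$cost
  unm <- problem$unmeasured
  meas <- problem$measured
  terms <- c(JMomres = 0, JMom = 0, JactSynX = 0, Jactres = 0, Jpen = 0)
  E1 <- tc$E_base
  if (problem$use_synx) {
    eSynX <- construct_unmeasured(tc$wm_unm,
                                  w$unmeasured$H[[tc$group_unm]],
                                  w$unmeasured$mu[[tc$group_unm]])
    E1[, unm] <- eSynX
    terms[["Jpen"]] <- sum(.range_excess(eSynX, cfg$mad_exc_penalty)^2)
  }
  f1 <- .forward_from_kinematics(E1, params, tc$kin, tc$n_pre,
                                 problem$curves, problem$g)
  Mpre <- f1$M[tc$cycle, , drop = FALSE]
  terms[["JMom"]] <- sum(((Mpre - tc$Mexp) / cfg$mad_mom)^2)
  if (problem$use_synx)
    terms[["JactSynX"]] <-
      sum((f1$a[tc$cycle, unm, drop = FALSE] / cfg$mad_act_synx)^2)
  f2 <- NULL; E2 <- NULL
  if (problem$use_res) {
    eres <- construct_residual(tc$wm_res, w$residual$H[[tc$group_res]],
                               w$residual$mu[[tc$group_res]])
    E2 <- E1
    E2[, meas] <- E2[, meas, drop = FALSE] + eres
    f2 <- .forward_from_kinematics(E2, params, tc$kin, tc$n_pre,
                                   problem$curves, problem$g)
    Mpreres <- f2$M[tc$cycle, , drop = FALSE]
    terms[["JMomres"]] <- sum(((Mpreres - tc$Mexp) / cfg$mad_mom_res)^2)
    ares <- f2$a[tc$cycle, meas, drop = FALSE] -
      f1$a[tc$cycle, meas, drop = FALSE]
    terms[["Jactres"]] <- sum((ares / cfg$mad_act_res)^2)
    terms[["Jpen"]] <- terms[["Jpen"]] +
      sum(.range_excess(E2[, meas, drop = FALSE], cfg$mad_exc_penalty)^2)
  }
  out <- list(terms = terms)
  if (details) {
    out$output <- list(
      Mpre = Mpre,
      Mpreres = if (problem$use_res) f2$M[tc$cycle, , drop = FALSE],
      Mexp = tc$Mexp,
      apre = f1$a[tc$cycle, , drop = FALSE],
      apreres = if (problem$use_res) f2$a[tc$cycle, , drop = FALSE],
      ares = if (problem$use_res)
        f2$a[tc$cycle, , drop = FALSE] - f1$a[tc$cycle, , drop = FALSE],
      eSynX = if (problem$use_synx) E1[, unm, drop = FALSE],
      eres = if (problem$use_res) E2[, meas, drop = FALSE] -
        E1[, meas, drop = FALSE])
  }
  out
}

# Stacked normalised residual vector of one trial (only the components the
# case keeps): the calibration cost is exactly sum(residuals^2), which the
# Levenberg-Marquardt path exploits.
.trial_residuals <- function(problem, tc, params, w) {
  cfg <- problem$cost
  unm <- problem$unmeasured
  meas <- problem$measured
  E1 <- tc$E_base
  if (problem$use_synx) {
    E1[, unm] <- construct_unmeasured(tc$wm_unm,
                                      w$unmeasured$H[[tc$group_unm]],
                                      w$unmeasured$mu[[tc$group_unm]])
  }
  f1 <- .forward_from_kinematics(E1, params, tc$kin, tc$n_pre,
                                 problem$curves, problem$g)
  out <- list(mom = as.numeric((f1$M[tc$cycle, , drop = FALSE] - tc$Mexp) /
                                 cfg$mad_mom))
  if (problem$use_synx) {
    out$act_synx <- as.numeric(f1$a[tc$cycle, unm, drop = FALSE] /
                                 cfg$mad_act_synx)
    out$pen <- .range_excess(E1[, unm, drop = FALSE], cfg$mad_exc_penalty)
  }
  if (problem$use_res) {
    eres <- construct_residual(tc$wm_res, w$residual$H[[tc$group_res]],
                               w$residual$mu[[tc$group_res]])
    E2 <- E1
    E2[, meas] <- E2[, meas, drop = FALSE] + eres
    f2 <- .forward_from_kinematics(E2, params, tc$kin, tc$n_pre,
                                   problem$curves, problem$g)
    out$mom_res <- as.numeric((f2$M[tc$cycle, , drop = FALSE] - tc$Mexp) /
                                cfg$mad_mom_res)
    out$act_res <- as.numeric((f2$a[tc$cycle, meas, drop = FALSE] -
                                 f1$a[tc$cycle, meas, drop = FALSE]) /
                                cfg$mad_act_res)
    out$pen_res <- .range_excess(E2[, meas, drop = FALSE],
                                 cfg$mad_exc_penalty)
  }
  unlist(out, use.names = FALSE)
}

# Which trials each design variable can influence: model parameters touch
# every trial; a weight variable only touches the trials of its group.
# Used by the structured finite-difference gradient.
.design_scopes <- function(problem) {
  scopes <- vector("list", problem$n_design)
  if (problem$n_par > 0)
    scopes[seq_len(problem$n_par)] <- list(names(problem$trials))
  lay <- problem$layout
  trials_of_group <- function(category) {
    ids <- names(problem$trials)
    split(ids, vapply(ids, .group_of_trial, character(1),
                      dataset = problem$dataset, category = category))
  }
  i <- problem$n_par
  if (lay$n_unmeasured > 0) {
    tg <- trials_of_group(lay$category_unmeasured)
    per <- (lay$p + 1L) * lay$q_unmeasured
    for (g in lay$groups_unmeasured) {
      scopes[i + seq_len(per)] <- list(tg[[g]])
      i <- i + per
    }
  }
  if (lay$n_residual > 0) {
    tg <- trials_of_group(lay$category_residual)
    per <- (lay$p + 1L) * lay$q_measured
    for (g in lay$groups_residual) {
      scopes[i + seq_len(per)] <- list(tg[[g]])
      i <- i + per
    }
  }
  scopes
}

#' Calibrate an EMG-driven model with synergy extrapolation
#'
#' The package's fitting function. Builds (or accepts) a [synx_problem()]
#' and solves it with a local least-squares method, optionally from
#' multiple seeded random starts. The default solver is
#' Levenberg-Marquardt on the stacked residual vector (box bounds enforced
#' smoothly through a sine transform; the finite-difference Jacobian
#' exploits the fact that a trial- or speed-specific weight only
#' influences its own trials); `optimizer = "lbfgsb"` selects a
#' bound-constrained quasi-Newton alternative on `[0, 1]`-scaled
#' variables. Initial guesses are mid-bounds for model parameters and zero
#' for synergy weights, with the unmeasured average values started at the
#' mean measured excitation level.
#'
#' @param dataset a [gait_dataset()] (ignored when `problem` is supplied).
#' @param geometry,params,case,n_synergies,category_unmeasured,category_residual,cost,bounds,fix_params
#'   passed to [synx_problem()].
#' @param problem optionally a prebuilt [synx_problem()].
#' @param control optimizer settings: `optimizer` (`"lm"` default, or
#'   `"lbfgsb"`), `maxit` (default 400), `multistart` (default 1), and the
#'   solver tolerances `ftol`/`ptol` (Levenberg-Marquardt) or `factr`
#'   (L-BFGS-B); `hops` (default 8 for the pure parameter case, else 0)
#'   sets the number of seeded basin hops over the length-scale subspace
#'   used to escape joint-compensation local minima; `x_init` overrides
#'   the initial design vector (natural units); `fd_step` is the
#'   forward-difference step on the scaled variables (default 1e-6).
#' @param seed integer seed for the multistart draws (and any other
#'   randomness); the fit is deterministic given the seed.
#' @return object of class `synx_fit`; see [coef.synx_fit()],
#'   [fitted.synx_fit()], [predict.synx_fit()].
#' @export
synx_calibrate <- function(dataset, geometry, params,
                           case = c("params_synx_res", "params_synx",
                                    "params"),
                           n_synergies = 6L,
                           category_unmeasured = "trial",
                           category_residual = "trial",
                           cost = cost_config(), bounds = synx_bounds(),
                           fix_params = FALSE, problem = NULL,
                           control = list(), seed = 1L) {
  if (is.null(problem)) {
    case <- match.arg(case)
    problem <- synx_problem(dataset, geometry, params, case, n_synergies,
                            category_unmeasured, category_residual,
                            cost, bounds, fix_params)
  }

  # With parameters frozen and all weight categories within-speed, the
  # problem separates exactly into independent per-speed problems (no
  # design variable couples trials of different speeds); solving them
  # separately is cheaper and better conditioned.
  speeds <- dataset_speeds(problem$dataset)
  separable <- problem$fix_params && problem$layout$length > 0 &&
    length(speeds) > 1 &&
    problem$layout$category_unmeasured != "subject" &&
    (!problem$use_res || problem$layout$category_residual != "subject")
  if (separable)
    return(.calibrate_by_speed(problem, control, seed))
  ctl <- utils::modifyList(list(optimizer = "lm", maxit = 400L,
                                factr = 1e7, multistart = 1L,
                                x_init = NULL, fd_step = 1e-6,
                                ftol = 1e-14, ptol = 1e-10,
                                hop_maxit = 80L,
                                hops = if (!is.null(problem) &&
                                             problem$case == "params")
                                  30L else 0L),
                           control)
  bnd <- .design_bounds(problem)
  span <- bnd$ub - bnd$lb
  to_nat <- function(s) bnd$lb + s * span
  to_scaled <- function(x) (x - bnd$lb) / span

  scopes <- .design_scopes(problem)
  keep <- .cost_terms_of_case(problem$case)
  ids_all <- names(problem$trials)
  trial_J <- function(des, ids) {
    vapply(ids, function(id)
      sum(.trial_cost(problem, problem$trials[[id]], des$params,
                      des$weights)$terms[keep]),
      numeric(1))
  }
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())
  fn <- function(s) {
    n_eval <<- n_eval + 1L
    des <- .unpack_design(problem, to_nat(s))
    jt <- trial_J(des, ids_all)
    cache$s <- s
    cache$jt <- jt
    v <- sum(jt)
    if (!is.finite(v)) 1e12 else v
  }
  # forward-difference gradient exploiting trial separability: a weight
  # variable of one trial/speed group only requires re-evaluating the
  # trials of that group
  h <- ctl$fd_step
  gr <- function(s) {
    if (is.null(cache$s) || !identical(cache$s, s)) fn(s)
    jt0 <- cache$jt
    x0 <- to_nat(s)
    grad <- numeric(length(s))
    for (i in seq_along(s)) {
      step <- if (s[i] + h <= 1) h else -h
      xi <- x0
      xi[i] <- bnd$lb[i] + (s[i] + step) * span[i]
      des <- .unpack_design(problem, xi)
      ids <- scopes[[i]]
      di <- sum(trial_J(des, ids)) - sum(jt0[ids])
      grad[i] <- if (is.finite(di)) di / step else 0
    }
    grad
  }

  # default start
  x0 <- numeric(problem$n_design)
  if (!problem$fix_params)
    x0[seq_len(problem$n_par)] <-
      (bnd$lb + bnd$ub)[seq_len(problem$n_par)] / 2
  if (problem$use_synx && problem$layout$n_unmeasured > 0) {
    w0 <- unpack_weights(problem$layout,
                         x0[problem$n_par + seq_len(problem$layout$length)])
    for (g_ in names(w0$unmeasured$mu))
      w0$unmeasured$mu[[g_]][] <- problem$mu_meas_mean
    x0[problem$n_par + seq_len(problem$layout$length)] <-
      pack_weights(problem$layout, w0$unmeasured, w0$residual)
  }
  if (!is.null(ctl$x_init)) x0 <- ctl$x_init
  starts <- list(to_scaled(x0))
  if (ctl$multistart > 1) {
    # structured extra starts first: shifting all length scale factors
    # together moves the fit between the joint-compensation basins of
    # the redundant muscle set; random starts fill any remainder
    if (!problem$fix_params) {
      nm_ <- length(problem$model_muscles)
      for (sc in c(0.9, 1.1, 0.85, 1.15, 0.95, 1.05)) {
        xs <- x0
        xs[4L * nm_ + seq_len(2L * nm_)] <- sc
        starts[[length(starts) + 1L]] <- to_scaled(xs)
      }
    }
    set.seed(seed)
    while (length(starts) < ctl$multistart)
      starts[[length(starts) + 1L]] <- stats::runif(problem$n_design)
    starts <- starts[seq_len(ctl$multistart)]
  }

  # Levenberg-Marquardt on the stacked residual vector (the cost is a sum
  # of squares); box bounds are enforced smoothly through a sine
  # transform, and the finite-difference Jacobian only re-evaluates the
  # trials a variable can influence.
  run_lm <- function(s0, free = seq_len(problem$n_design),
                     maxiter = ctl$maxit) {
    s0 <- pmin(pmax(s0, 1e-3), 1 - 1e-3)
    x_fix <- to_nat(s0)
    # the sine transform is periodic, so shifting z by 2*pi changes
    # nothing -- except that lmder sizes its initial trust region from
    # ||diag * par||, which collapses for a near-zero start
    z0 <- asin(2 * s0[free] - 1) + 2 * pi
    z_to_x <- function(z) {
      x <- x_fix
      x[free] <- bnd$lb[free] + span[free] * (sin(z) + 1) / 2
      x
    }
    res_by_trial <- function(des, ids) {
      lapply(stats::setNames(nm = ids), function(id)
        .trial_residuals(problem, problem$trials[[id]], des$params,
                         des$weights))
    }
    lm_cache <- new.env(parent = emptyenv())
    resfun <- function(z) {
      n_eval <<- n_eval + 1L
      des <- .unpack_design(problem, z_to_x(z))
      rt <- res_by_trial(des, ids_all)
      lm_cache$z <- z
      lm_cache$rt <- rt
      r <- unlist(rt, use.names = FALSE)
      r[!is.finite(r)] <- 1e6
      r
    }
    jacfun <- function(z) {
      if (is.null(lm_cache$z) || !identical(lm_cache$z, z)) resfun(z)
      rt0 <- lm_cache$rt
      len <- lengths(rt0)
      offset <- stats::setNames(cumsum(c(0L, len[-length(len)])), ids_all)
      x0_ <- z_to_x(z)
      J <- matrix(0, sum(len), length(z))
      dz <- 1e-6
      for (i in seq_along(z)) {
        v <- free[i]
        zi <- z
        zi[i] <- zi[i] + dz
        xi <- x0_
        xi[v] <- bnd$lb[v] + span[v] * (sin(zi[i]) + 1) / 2
        des <- .unpack_design(problem, xi)
        for (id in scopes[[v]]) {
          ri <- .trial_residuals(problem, problem$trials[[id]],
                                 des$params, des$weights)
          J[offset[[id]] + seq_along(ri), i] <- (ri - rt0[[id]]) / dz
        }
      }
      J
    }
    opt <- minpack.lm::nls.lm(
      par = z0, fn = resfun, jac = jacfun,
      control = minpack.lm::nls.lm.control(
        maxiter = min(maxiter, 1024L), ftol = ctl$ftol,
        ptol = ctl$ptol, maxfev = 100000L))
    list(par = to_scaled(z_to_x(opt$par)), value = opt$deviance,
         convergence = if (opt$info %in% c(1L, 2L, 3L, 4L)) 0L else 1L,
         counts = c(`function` = opt$niter, gradient = NA),
         message = opt$message)
  }

  run_lbfgsb <- function(s0) {
    cache$s <- NULL
    stats::optim(s0, fn, gr, method = "L-BFGS-B",
                 lower = rep(0, problem$n_design),
                 upper = rep(1, problem$n_design),
                 control = list(maxit = ctl$maxit, factr = ctl$factr))
  }

  best <- NULL
  for (s0 in starts) {
    opt <- if (ctl$optimizer == "lm") run_lm(s0) else run_lbfgsb(s0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  # Redundant muscle sets admit joint-compensation local minima: several
  # muscles' length scale factors drift together while the moment error
  # stays tiny. Seeded basin hops over the scale-factor subspace (with
  # activation parameters kept warm) escape these basins reliably on the
  # pure parameter-calibration case; a global optimum is recognisable on
  # noiseless data by an essentially zero cost, which stops the hops
  # early.
  if (ctl$optimizer == "lm" && !problem$fix_params && ctl$hops > 0 &&
      best$value > 1e-8) {
    nm_ <- length(problem$model_muscles)
    # hop groups: the muscles sharing a DOF (whose scale factors can
    # compensate each other), plus the full muscle set
    r1 <- problem$trials[[1]]$kin$r
    groups <- lapply(seq_len(dim(r1)[3]), function(d)
      which(apply(abs(r1[, , d, drop = FALSE]), 2L, max) > 1e-9))
    groups <- c(groups[lengths(groups) > 1], list(seq_len(nm_)))
    set.seed(seed + 1000L)
    for (hop in seq_len(ctl$hops)) {
      g_ <- groups[[(hop - 1L) %% length(groups) + 1L]]
      s_try <- best$par
      s_try[4L * nm_ + g_] <-
        (stats::runif(length(g_), 0.85, 1.15) - 0.6) / 0.8
      s_try[5L * nm_ + g_] <-
        (stats::runif(length(g_), 0.9, 1.1) - 0.6) / 0.8
      cand_fit <- suppressWarnings(run_lm(s_try, maxiter = ctl$hop_maxit))
      if (cand_fit$value < best$value)
        best <- suppressWarnings(run_lm(cand_fit$par))
      if (best$value <= 1e-8) break
    }
  }

  x_hat <- to_nat(best$par)
  final <- evaluate_cost(problem, x_hat, details = TRUE)
  des <- .unpack_design(problem, x_hat)
  structure(
    list(problem = problem, case = problem$case,
         params = des$params, weights = des$weights,
         design = x_hat, cost = final$J, terms = final$terms,
         outputs = final$outputs,
         convergence = best$convergence == 0,
         optim = list(value = best$value, counts = best$counts,
                      convergence = best$convergence,
                      message = best$message, n_eval = n_eval),
         seed = seed),
    class = "synx_fit")
}

# Solve a speed-separable weights-only problem as independent per-speed
# calibrations and merge the results into one synx_fit.
.calibrate_by_speed <- function(problem, control, seed) {
  ds <- problem$dataset
  speeds <- dataset_speeds(ds)
  sub_fits <- lapply(speeds, function(sp) {
    ids <- names(ds$trials)[vapply(ds$trials, function(t)
      t$speed_label == sp, logical(1))]
    sub <- gait_dataset(ds$trials[ids], ds$unmeasured_muscles)
    sub_problem <- synx_problem(sub, problem$geometry, problem$params,
                               case = problem$case,
                               n_synergies = problem$n_synergies,
                               category_unmeasured =
                                 problem$layout$category_unmeasured,
                               category_residual =
                                 problem$layout$category_residual,
                               cost = problem$cost,
                               bounds = problem$bounds,
                               fix_params = TRUE,
                               curves = problem$curves, g = problem$g)
    synx_calibrate(problem = sub_problem, control = control, seed = seed)
  })
  names(sub_fits) <- speeds

  merge_side <- function(side) {
    sets <- lapply(sub_fits, function(f) f$weights[[side]])
    sets <- sets[!vapply(sets, is.null, logical(1))]
    if (length(sets) == 0) return(NULL)
    synx_weights(do.call(c, lapply(sets, `[[`, "H")) |>
                   stats::setNames(unlist(lapply(sets, function(s)
                     names(s$H)))),
                 do.call(c, lapply(sets, `[[`, "mu")) |>
                   stats::setNames(unlist(lapply(sets, function(s)
                     names(s$mu)))),
                 sets[[1]]$category)
  }
  weights <- list(unmeasured = merge_side("unmeasured"),
                  residual = merge_side("residual"))
  x_hat <- pack_weights(problem$layout, weights$unmeasured,
                        weights$residual)
  outputs <- do.call(c, lapply(sub_fits, `[[`, "outputs"))
  names(outputs) <- unlist(lapply(sub_fits, function(f)
    names(f$outputs)))
  outputs <- outputs[names(ds$trials)]
  terms <- Reduce(`+`, lapply(sub_fits, `[[`, "terms"))
  structure(
    list(problem = problem, case = problem$case,
         params = problem$params, weights = weights,
         design = x_hat, cost = sum(vapply(sub_fits, `[[`, numeric(1),
                                           "cost")),
         terms = terms, outputs = outputs,
         convergence = all(vapply(sub_fits, `[[`, logical(1),
                                  "convergence")),
         optim = list(
           value = sum(vapply(sub_fits, function(f) f$optim$value,
                              numeric(1))),
           counts = Reduce(`+`, lapply(sub_fits, function(f)
             f$optim$counts)),
           convergence = max(vapply(sub_fits, function(f)
             f$optim$convergence, numeric(1))),
           message = paste(vapply(sub_fits, function(f)
             paste(f$optim$message, collapse = " "), character(1)),
             collapse = " | "),
           n_eval = sum(vapply(sub_fits, function(f) f$optim$n_eval,
                               numeric(1)))),
         seed = seed),
    class = "synx_fit")
}
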