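# Calibration problems: cost evaluation, case structure, and guards.
# The long-running recovery experiments live in test-acceptance.R.

make_problem <- function(case = "params_synx_res", cat_u = "trial",
                         cat_r = "speed", fix = TRUE, ...) {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  synx_problem(ds, syn$geometry, syn$params_true, case = case,
               n_synergies = 6, category_unmeasured = cat_u,
               category_residual = cat_r, fix_params = fix, ...)
}

test_that("cost at ground truth vanishes for the params case", {
  syn <- cached_synthetic(seed = 7)
  prob <- synx_problem(syn$dataset, syn$geometry, syn$params_true,
                       case = "params", fix_params = FALSE)
  # design vector = true parameter values, no weights
  x <- unlist(lapply(c("semg", "d", "tau_act", "c3", "scale_lo",
                       "scale_ls"),
                     function(f) syn$params_true[[f]]))
  v <- evaluate_cost(prob, x)
  expect_lt(v$J, 1e-10)
  expect_identical(unname(v$terms[c("JMomres", "JactSynX", "Jactres")]),
                   c(0, 0, 0))
})

test_that("cost matches a hand-computed sum of squares on a tiny problem", {
  # 2 muscles, 1 DOF, constant signals: every quantity is computable by
  # hand through the closed-form steady state
  syn <- cached_synthetic(seed = 7)
  prob <- synx_problem(syn$dataset, syn$geometry, syn$params_true,
                       case = "params", fix_params = TRUE)
  v <- evaluate_cost(prob, numeric(0), details = TRUE)
  # spreadsheet-style oracle: recompute JMom from the stored outputs
  acc <- 0
  for (o in v$outputs)
    acc <- acc + sum(((o$Mpre - o$Mexp) / prob$cost$mad_mom)^2)
  expect_equal(v$J, acc, tolerance = 1e-12)
  expect_equal(v$J, 0, tolerance = 1e-10)  # params frozen at truth
})

test_that("MAD scaling acts quadratically on its term", {
  syn <- cached_synthetic(seed = 7)
  base <- synx_problem(syn$dataset, syn$geometry, syn$params_nominal,
                       case = "params", fix_params = TRUE)
  doubled <- synx_problem(syn$dataset, syn$geometry, syn$params_nominal,
                          case = "params", fix_params = TRUE,
                          cost = cost_config(mad_mom = 2 *
                                               cost_config()$mad_mom))
  j1 <- evaluate_cost(base, numeric(0))$J
  j2 <- evaluate_cost(doubled, numeric(0))$J
  expect_gt(j1, 0)  # nominal parameters do not match the truth-run moments
  expect_equal(j2, j1 / 4, tolerance = 1e-12)
})

test_that("case nesting: zero residual weights reduce to params_synx", {
  prob_full <- make_problem("params_synx_res")
  prob_synx <- make_problem("params_synx", cat_u = "trial", cat_r = "trial")
  set.seed(33)
  for (i in 1:3) {
    xu <- rnorm(prob_synx$layout$length, 0, 0.2)
    x_full <- c(xu, numeric(prob_full$layout$n_residual))
    v_full <- evaluate_cost(prob_full, x_full)
    v_synx <- evaluate_cost(prob_synx, xu)
    # with eres = 0: Mpreres = Mpre, so JMomres = JMom * (MAD2/MAD1)^2,
    # ares = 0, and the shared terms agree exactly
    expect_equal(v_full$terms[["JMom"]], v_synx$terms[["JMom"]],
                 tolerance = 1e-10)
    expect_equal(v_full$terms[["JactSynX"]], v_synx$terms[["JactSynX"]],
                 tolerance = 1e-10)
    expect_equal(v_full$terms[["JMomres"]],
                 v_full$terms[["JMom"]] *
                   (prob_full$cost$mad_mom / prob_full$cost$mad_mom_res)^2,
                 tolerance = 1e-10)
    expect_equal(v_full$terms[["Jactres"]], 0)
  }
})

test_that("non-finite model outputs yield a non-finite cost, not a crash", {
  prob <- make_problem()
  x <- numeric(prob$n_design)
  x[1] <- NaN
  v <- evaluate_cost(prob, x)
  expect_false(is.finite(v$J))
})

test_that("problem construction validates its inputs", {
  syn <- cached_synthetic(seed = 7)
  expect_error(synx_problem(syn$dataset, syn$geometry, syn$params_true,
                            case = "params_synx"),
               "unmeasured muscle set")
  expect_error(cost_config(mad_mom = -1), "positive")
  lay_prob <- make_problem()
  expect_identical(lay_prob$n_design, 280L)  # 140 unmeasured + 140 residual
  prob_p <- synx_problem(syn$dataset, syn$geometry, syn$params_true,
                         case = "params")
  expect_identical(prob_p$n_design, 72L)     # 6 parameters x 12 muscles
  expect_identical(prob_p$layout$length, 0L)
})

test_that("design scopes map weight variables to their own trials", {
  prob <- make_problem()  # trial-specific unmeasured, speed-specific res
  scopes <- synx:::.design_scopes(prob)
  expect_length(scopes, 280)
  # first unmeasured block belongs to trial_01 only
  expect_identical(scopes[[1]], "trial_01")
  # residual blocks cover the five trials of one speed
  expect_length(scopes[[141]], 5)
  ds <- holdout_muscles(cached_synthetic(seed = 7))
  sp <- vapply(ds$trials[scopes[[141]]], function(t) t$speed_label,
               character(1))
  expect_length(unique(sp), 1)
})

test_that("a short calibration respects bounds and decreases the cost", {
  syn <- cached_synthetic(seed = 7)
  fit <- synx_calibrate(syn$dataset, syn$geometry, syn$params_nominal,
                        case = "params", control = list(maxit = 3),
                        seed = 1)
  p <- coef(fit)
  expect_true(all(p$semg >= 0.05 - 1e-9 & p$semg <= 1 + 1e-9))
  expect_true(all(p$scale_lo >= 0.6 - 1e-9 & p$scale_lo <= 1.4 + 1e-9))
  expect_true(all(p$scale_ls >= 0.6 - 1e-9 & p$scale_ls <= 1.4 + 1e-9))
  expect_true(all(p$d >= 0 & p$d <= 0.1 + 1e-9))
  # cost decreased relative to the nominal start
  x0 <- unlist(lapply(c("semg", "d", "tau_act", "c3", "scale_lo",
                        "scale_ls"),
                      function(f)
                        (synx_bounds()[[switch(f, scale_lo = ,
                                               scale_ls = "scale", f)]] |>
                           mean()) |> rep(12)))
  j0 <- evaluate_cost(fit$problem, x0)$J
  expect_lt(fit$cost, j0)
})

test_that("validation guards reject trial-specific weights", {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  fit <- synx_calibrate(ds, syn$geometry, syn$params_true,
                        case = "params_synx", n_synergies = 4,
                        category_unmeasured = "trial", fix_params = TRUE,
                        control = list(maxit = 2), seed = 1)
  expect_error(predict(fit, ds), "cannot transfer")
  fitp <- synx_calibrate(syn$dataset, syn$geometry, syn$params_true,
                         case = "params", control = list(maxit = 2),
                         seed = 1)
  expect_error(predict(fitp, ds), "SynX case")
})

test_that("calibration is deterministic given the seed", {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  f1 <- synx_calibrate(ds, syn$geometry, syn$params_true,
                       case = "params_synx", n_synergies = 4,
                       category_unmeasured = "speed", fix_params = TRUE,
                       control = list(maxit = 4, multistart = 2), seed = 9)
  f2 <- synx_calibrate(ds, syn$geometry, syn$params_true,
                       case = "params_synx", n_synergies = 4,
                       category_unmeasured = "speed", fix_params = TRUE,
                       control = list(maxit = 4, multistart = 2), seed = 9)
  expect_identical(f1$design, f2$design)
  expect_identical(f1$cost, f2$cost)
})
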