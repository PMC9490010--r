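# The EMG-driven forward chain: activation dynamics, activation
# nonlinearity, rigid-tendon Hill force, geometry and net joint moments.

test_that("activation rate constants follow the tied-deactivation rule", {
  cc <- compute_c_constants(0.02)
  expect_equal(cc$c1, 37.5)   # 1/0.02 - 1/0.08
  expect_equal(cc$c2, 12.5)   # 1/0.08
  cc <- compute_c_constants(0.25)
  expect_equal(cc$c2, 1.0)
  # c1/c2 = 3 for any tau_act under tau_dact = 4 tau_act
  for (tau in c(0.01, 0.033, 0.05))
    with(compute_c_constants(tau), NULL)
  ratios <- vapply(c(0.01, 0.033, 0.05), function(tau) {
    cc <- compute_c_constants(tau); cc$c1 / cc$c2
  }, numeric(1))
  expect_equal(ratios, rep(3, 3))
  expect_error(compute_c_constants(0), "positive")
})

test_that("activation dynamics has the constant-excitation fixed point", {
  dt <- 0.01
  e <- matrix(0.63, 200, 1)
  u <- activation_dynamics(e, tau_act = 0.02, d = 0, dt = dt)
  # after 5 * tau_dact the state has settled to e
  expect_lt(max(abs(u[50:200, 1] - 0.63)), 1e-4)
  u0 <- activation_dynamics(matrix(0, 100, 1), 0.02, 0, dt)
  expect_true(all(u0 == 0))
})

test_that("step response matches the constant-coefficient closed form", {
  dt <- 0.001
  tau <- 0.015
  n <- 400
  e <- matrix(c(rep(0, 100), rep(1, n - 100)), ncol = 1)
  u <- activation_dynamics(e, tau, d = 0, dt = dt)
  cc <- compute_c_constants(tau)
  rate <- cc$c1 * 1 + cc$c2
  t_after <- (seq_len(n) - 101) * dt
  closed <- ifelse(t_after < 0, 0, 1 - exp(-rate * t_after))
  expect_lt(max(abs(u[, 1] - closed)), 0.01)
})

test_that("the delay shifts excitation in real time", {
  dt <- 0.012
  n <- 121
  ph <- (seq_len(n) - 21) / 100
  e <- matrix(0.5 + 0.4 * sin(2 * pi * ph), ncol = 1)
  d <- 0.06  # 5 frames
  u_delayed <- activation_dynamics(e, 0.02, d = d, dt = dt)
  e_shifted <- matrix(c(rep(e[1], 5), e[1:(n - 5)]), ncol = 1)
  u_manual <- activation_dynamics(e_shifted, 0.02, d = 0, dt = dt)
  expect_lt(max(abs(u_delayed - u_manual)), 1e-10)
  expect_error(activation_dynamics(e, 0.02, d = 0.3, dt = dt),
               "pre-frame buffer")
})

test_that("activation nonlinearity is anchored and collapses at c3 = 0", {
  u <- matrix(seq(0, 1, 0.1), ncol = 1)
  expect_equal(activation_nonlinearity(u, 0), u)
  a <- activation_nonlinearity(u, 0.5)
  expect_equal(a[1, 1], 0, tolerance = 1e-6)
  expect_equal(a[11, 1], 1, tolerance = 1e-6)
  expect_true(all(diff(a[, 1]) > 0))  # monotone
  # duplicate-formula oracle at c3 = 0.5
  g <- default_g_constants()
  want <- (1 - 0.5) * u + 0.5 * (g["g1"] * g["g2"]^((u + g["g3"])^g["g4"]) +
                                   g["g5"] + 1)
  expect_lt(max(abs(a - want)), 1e-12)
  expect_error(activation_nonlinearity(u, 1), "c3")
})

test_that("fiber kinematics follow the rigid-tendon relations", {
  k <- normalized_fiber_kinematics(0.25, 0, lo = 0.10, ls = 0.15)
  expect_equal(k$l, 1.0)
  expect_equal(k$v, 0)
  expect_equal(normalized_fiber_kinematics(0.25, 0.5, 0.10, 0.15)$v, 0.5)
  expect_error(normalized_fiber_kinematics(0.2, 0, 0, 0.1), "positive")
})

test_that("muscle force honours the Hill normalisations", {
  expect_equal(muscle_force(1, 1, 0, fmax = 1234, alpha = 0), 1234)
  # passive slack below optimal length, zero activation -> zero force
  expect_equal(muscle_force(0, 0.8, 0, fmax = 1000), 0)
  # duplicate-formula evaluation at a generic point
  crv <- default_muscle_curves()
  a <- 0.5; l <- 0.9; v <- -0.3; al <- 0.2
  want <- 1000 * (a * crv$fl(l) * crv$fv(v) + crv$fp(l)) * cos(al)
  expect_equal(muscle_force(a, l, v, 1000, al), want, tolerance = 1e-12)
  # force-velocity endpoints: fv(0) = 1, fv(-1) = 0
  expect_equal(crv$fv(0), 1)
  expect_equal(crv$fv(-1), 0)
  # force is non-decreasing in activation
  fs <- muscle_force(seq(0, 1, 0.1), 1.05, 0.1, 800)
  expect_true(all(diff(fs) >= 0))
})

test_that("net joint moments sum force times moment arm", {
  F <- matrix(100, 1, 1)
  r <- array(0.05, c(1, 1, 1))
  expect_equal(as.numeric(net_joint_moments(F, r)), 5)
  # antagonist cancellation
  F2 <- matrix(c(50, 50), 1)
  r2 <- array(c(0.04, -0.04), c(1, 2, 1))
  expect_equal(as.numeric(net_joint_moments(F2, r2)), 0)
  # seeded triple-loop oracle
  set.seed(13)
  F3 <- matrix(runif(121 * 4), 121)
  r3 <- array(runif(121 * 4 * 3, -0.05, 0.05), c(121, 4, 3))
  got <- net_joint_moments(F3, r3)
  want <- matrix(0, 121, 3)
  for (i in 1:121) for (d in 1:3) for (m in 1:4)
    want[i, d] <- want[i, d] + F3[i, m] * r3[i, m, d]
  expect_lt(max(abs(got - want)), 1e-12)
  expect_error(net_joint_moments(F3[1:5, ], r3), "shape")
})

test_that("surrogate polynomial fits recover lengths and moment arms", {
  # linear length function: constant moment arm, zero residual
  th <- matrix(seq(-0.5, 0.5, length.out = 21),
               dimnames = list(NULL, "dof1"))
  samples <- list(m1 = list(theta = th, lmt = 0.3 - 0.05 * th[, 1]))
  sg <- fit_surrogate(samples, dof_names = c("dof1", "dof2"), degree = 2)
  expect_lt(sg$max_residual[["m1"]], 1e-12)
  thq <- cbind(dof1 = c(-0.3, 0, 0.4), dof2 = 0)
  expect_equal(unname(moment_arms(sg, thq)[, "m1", "dof1"]),
               rep(0.05, 3), tolerance = 1e-10)
  # non-spanned DOF has identically zero moment arm
  expect_true(all(moment_arms(sg, thq)[, "m1", "dof2"] == 0))

  # sinusoidal lMT: degree-5 fit matches the analytic moment arm
  samples2 <- list(m2 = list(theta = th,
                             lmt = 0.3 - 0.04 * sin(th[, 1])))
  sg2 <- fit_surrogate(samples2, "dof1", degree = 5)
  grid <- cbind(dof1 = seq(-0.45, 0.45, length.out = 40))
  got <- moment_arms(sg2, grid)[, "m2", "dof1"]
  expect_lt(max(abs(got - 0.04 * cos(grid[, 1]))), 1e-4)
})

test_that("rank-deficient surrogate designs are rejected with advice", {
  th <- matrix(rep(0.2, 5), dimnames = list(NULL, "dof1"))
  expect_error(fit_surrogate(list(m = list(theta = th, lmt = rep(0.3, 5))),
                             "dof1", degree = 3),
               "lower the degree")
})

test_that("surrogate moment arms match finite differences of lMT", {
  fix <- planar_leg_fixture()
  ranges <- list(hip_fe = c(-0.5, 0.6), hip_aa = c(-0.2, 0.15),
                 knee_fe = c(-0.2, 1.0), ankle_pd = c(-0.35, 0.35))
  sg <- fit_surrogate(sample_geometry(fix$geometry, ranges),
                      dof_names = c("hip_fe", "hip_aa", "knee_fe",
                                    "ankle_pd"),
                      degree = 5)
  set.seed(21)
  th <- cbind(hip_fe = runif(7, -0.4, 0.5), hip_aa = runif(7, -0.15, 0.1),
              knee_fe = runif(7, -0.1, 0.9),
              ankle_pd = runif(7, -0.3, 0.3))
  h <- 1e-5
  r <- moment_arms(sg, th)
  for (d in colnames(th)) {
    thp <- th; thp[, d] <- thp[, d] + h
    thm <- th; thm[, d] <- thm[, d] - h
    fd <- -(muscle_tendon_lengths(sg, thp) -
              muscle_tendon_lengths(sg, thm)) / (2 * h)
    rel <- abs(r[, , d] - fd) / pmax(abs(fd), 1e-4)
    expect_lt(max(rel), 1e-6)
  }
  # and the surrogate reproduces the analytic fixture arms closely
  ra <- moment_arms(fix$geometry, th)
  expect_lt(max(abs(r - ra)), 1e-4)
})

test_that("muscle-tendon velocity is the moment-arm weighted angle rate", {
  fix <- planar_leg_fixture()
  th <- matrix(c(0.2, -0.05, 0.4, -0.1), 1,
               dimnames = list(NULL, c("hip_fe", "hip_aa", "knee_fe",
                                       "ankle_pd")))
  thd <- matrix(c(1.5, 0.4, -2.0, 0.7), 1, dimnames = dimnames(th))
  v <- muscle_tendon_velocities(fix$geometry, th, thd)
  r <- moment_arms(fix$geometry, th)
  want <- -(r[, , 1] * thd[1, 1] + r[, , 2] * thd[1, 2] +
              r[, , 3] * thd[1, 3] + r[, , 4] * thd[1, 4])
  expect_equal(as.numeric(v), as.numeric(want), tolerance = 1e-12)
})

test_that("forward chain composes and is superposable over muscles", {
  syn <- cached_synthetic(seed = 7)
  tr <- syn$dataset$trials[[1]]
  p <- syn$params_true
  fwd <- forward_chain(tr, p, syn$geometry)
  expect_identical(dim(fwd$M), c(121L, ncol(tr$joint_angles)))
  # zero excitations with no passive stretch -> zero active contribution
  E0 <- tr$excitations * 0
  f0 <- forward_chain(tr, p, syn$geometry, excitations = E0)
  expect_true(all(f0$a < 1e-12))
  # Eq-13 superposition: single-muscle moment contributions sum to total
  total <- fwd$M
  acc <- 0
  for (m in rownames(p)) {
    Em <- E0; Em[, m] <- tr$excitations[, m]
    acc <- acc + forward_chain(tr, p, syn$geometry, excitations = Em)$M
  }
  # passive force of the other muscles is counted once per single run
  n_extra <- length(rownames(p)) - 1
  passive <- f0$M
  expect_lt(max(abs(acc - n_extra * passive - total)), 1e-8)
})

test_that("forward chain at truth reproduces stored noiseless moments", {
  syn <- cached_synthetic(seed = 7)
  for (id in names(syn$dataset$trials)[c(1, 6)]) {
    tr <- syn$dataset$trials[[id]]
    fwd <- forward_chain(tr, syn$params_true, syn$geometry,
                         excitations = syn$truth$excitations[[id]])
    expect_lt(max(abs(fwd$M - syn$truth$moments[[id]])), 1e-8)
    # generator default: noiseless moments are the stored ID moments
    expect_lt(max(abs(fwd$M - tr$id_moments)), 1e-8)
  }
})

test_that("muscle parameter bounds are validated", {
  expect_error(muscle_params("m", semg = 0.01), "semg")
  expect_error(muscle_params("m", d = 0.5), "delay")
  expect_error(muscle_params("m", scale_lo = 1.6), "scale factors")
})
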