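# The synthetic gait generator and planar-leg fixture.

test_that("the generator is deterministic under its seed", {
  a <- generate_synthetic_gait(synthetic_config(seed = 5))
  b <- generate_synthetic_gait(synthetic_config(seed = 5))
  expect_identical(a$dataset$trials[[3]]$excitations,
                   b$dataset$trials[[3]]$excitations)
  expect_identical(a$params_true, b$params_true)
  c <- generate_synthetic_gait(synthetic_config(seed = 6))
  expect_false(identical(a$dataset$trials[[3]]$excitations,
                         c$dataset$trials[[3]]$excitations))
})

test_that("default dimensions and structure match the protocol", {
  syn <- cached_synthetic(seed = 7)
  expect_length(syn$dataset$trials, 10)
  sp <- table(vapply(syn$dataset$trials, function(t) t$speed_label,
                     character(1)))
  expect_true(all(sp == 5))
  expect_identical(dim(syn$dataset$trials[[1]]$excitations), c(121L, 12L))
  expect_identical(syn$unmeasured_candidates, c("iliacus", "psoas"))
  # excitations normalised to max 1 over trials, in [0, 1]
  mx <- Reduce(pmax, lapply(syn$truth$excitations,
                            function(E) apply(E, 2L, max)))
  expect_equal(unname(mx), rep(1, 12), tolerance = 1e-12)
})

test_that("noiseless measured excitations are exactly rank p* per trial", {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  for (E in concatenate_excitations(ds, "trial")[c(1, 7)]) {
    dec <- pca_decompose(E, 5)
    expect_gt(compute_vaf(E, synergy_reconstruct(dec)), 100 - 1e-8)
  }
})

test_that("synergy-count selection at 95% returns the true p*", {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  E <- concatenate_excitations(ds, "subject")[[1]]
  expect_identical(select_num_synergies(E, 95), 5L)
})

test_that("held-out truth lies exactly in span(Wm) + mean when noiseless", {
  syn <- cached_synthetic(seed = 7)
  ds <- holdout_muscles(syn)
  decs <- decompose_dataset(ds, 5, "trial")
  for (id in c("trial_01", "trial_09")) {
    wm <- synx:::.wm_for_trial(decs, id)$Wm
    truth <- syn$truth$excitations[[id]][, ds$unmeasured_muscles]
    X <- cbind(wm, 1)
    proj <- X %*% qr.solve(X, truth)
    expect_lt(max(abs(proj - truth)), 1e-8)
  }
})

test_that("holdout bookkeeping updates the partition only", {
  syn <- cached_synthetic(seed = 7)
  full <- syn$dataset
  expect_identical(holdout_muscles(full, character()), full)
  held <- holdout_muscles(full, c("iliacus", "psoas"))
  expect_length(held$measured_muscles, 10)
  expect_setequal(held$unmeasured_muscles, c("iliacus", "psoas"))
  expect_identical(held$trials, full$trials)
  expect_error(holdout_muscles(full, "not_a_muscle"), "unknown")
})

test_that("speed-shared weights make trial- and speed-level MSA agree", {
  syn0 <- generate_synthetic_gait(synthetic_config(
    seed = 3, weight_variability = "speed",
    shape_jitter_amp = 0, shape_jitter_phase = 0))
  ds0 <- holdout_muscles(syn0)
  dt <- decompose_dataset(ds0, 5, "trial")
  dsp <- decompose_dataset(ds0, 5, "speed")
  # per-speed weights equal each member trial's weights up to sign
  for (sp in names(dsp)) {
    for (id in names(dsp[[sp]]$frame_partition)) {
      for (j in 1:5) {
        d <- min(max(abs(dt[[id]]$Hm[j, ] - dsp[[sp]]$Hm[j, ])),
                 max(abs(dt[[id]]$Hm[j, ] + dsp[[sp]]$Hm[j, ])))
        expect_lt(d, 1e-8)
      }
    }
  }
})

test_that("the planar fixture has analytic arms and antagonist pairs", {
  fix <- planar_leg_fixture()
  th <- matrix(c(0.3, -0.05, 0.5, -0.1), 1,
               dimnames = list(NULL, c("hip_fe", "hip_aa", "knee_fe",
                                       "ankle_pd")))
  r <- moment_arms(fix$geometry, th)
  # symbolic: r = rho * cos(theta + phi) for iliacus at the hip
  expect_equal(r[1, "iliacus", "hip_fe"], 0.035 * cos(0.3 - 0.15))
  # finite-difference agreement
  h <- 1e-6
  thp <- th; thp[1, "hip_fe"] <- thp[1, "hip_fe"] + h
  fd <- -(muscle_tendon_lengths(fix$geometry, thp)[, "iliacus"] -
            muscle_tendon_lengths(fix$geometry, th)[, "iliacus"]) / h
  expect_equal(unname(r[1, "iliacus", "hip_fe"]), unname(fd),
               tolerance = 1e-5)
  # hip flexor vs extensor produce opposing moments
  expect_lt(r[1, "glut_max", "hip_fe"] * r[1, "iliacus", "hip_fe"], 0)
  # ankle plantarflexor vs dorsiflexor
  expect_lt(r[1, "soleus", "ankle_pd"] * r[1, "tib_ant", "ankle_pd"], 0)
  # infeasible configs are rejected
  expect_error(synthetic_config(n_unmeasured = 12), "smaller")
  expect_error(synthetic_config(n_synergies_true = 11), "exceed")
})

test_that("surrogate fitted to the sampled fixture matches analytic arms", {
  fix <- planar_leg_fixture()
  ranges <- list(hip_fe = c(-0.5, 0.6), hip_aa = c(-0.2, 0.15),
                 knee_fe = c(-0.2, 1.0), ankle_pd = c(-0.35, 0.35))
  sg <- fit_surrogate(sample_geometry(fix$geometry, ranges),
                      dof_names = c("hip_fe", "hip_aa", "knee_fe",
                                    "ankle_pd"),
                      degree = 5)
  syn <- cached_synthetic(seed = 7)
  th <- syn$dataset$trials[[1]]$joint_angles
  expect_lt(max(abs(moment_arms(sg, th) -
                      moment_arms(fix$geometry, th))), 1e-4)
})
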