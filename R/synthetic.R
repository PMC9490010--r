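# Synthetic gait datasets with known ground truth: synergy-structured
# excitations, a planar-leg analytic geometry, true muscle-tendon
# parameters, and forward-computed "experimental" joint moments. Every
# calibration and SynX recovery experiment in the package is testable
# against the stored truth.

#' Configuration of the synthetic gait-data generator
#'
#' Defaults emulate a two-speed treadmill protocol: 5 gait cycles per speed
#' at a self-selected and a fastest-comfortable speed, 121-frame cycles,
#' 12 muscles over 4 lower-limb DOFs (hip flexion/extension, hip
#' add/abduction, knee flexion, ankle plantar/dorsiflexion) of which 2
#' deep hip flexors (iliacus, psoas) are candidates for holding out, and
#' 5 underlying synergies.
#'
#' @param n_muscles total muscles (default 12).
#' @param n_unmeasured muscles designated for hold-out (default 2; the
#'   first `n_unmeasured` names are "iliacus", "psoas", ...).
#' @param n_synergies_true number of generating synergies p* (default 5).
#' @param n_trials_per_speed gait cycles per speed (default 5).
#' @param speeds speed labels (default self-selected and fastest).
#' @param noise_sd_excitation additive Gaussian noise SD on excitations
#'   (clipped to `[0, 1]` afterwards; default 0).
#' @param noise_sd_moment additive Gaussian noise SD on the "experimental"
#'   moments, N*m (default 0).
#' @param weight_variability how the true synergy weights vary across
#'   trials: `"trial"`, `"speed"` or `"subject"` (default `"trial"`).
#' @param shape_jitter_amp,shape_jitter_phase between-trial variability of
#'   the synergy excitation shapes: relative amplitude jitter (default
#'   0.07) and phase jitter in cycle fraction (default 0.015). Set both to
#'   0 for trials whose synergy excitations are identical up to the time
#'   grid (useful for category-identity checks).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_muscles = 12L, n_unmeasured = 2L,
                             n_synergies_true = 5L,
                             n_trials_per_speed = 5L,
                             speeds = c("self-selected", "fastest"),
                             noise_sd_excitation = 0,
                             noise_sd_moment = 0,
                             weight_variability = c("trial", "speed",
                                                    "subject"),
                             shape_jitter_amp = 0.07,
                             shape_jitter_phase = 0.015,
                             seed = 1L) {
  weight_variability <- match.arg(weight_variability)
  if (n_unmeasured >= n_muscles)
    stop("n_unmeasured must be smaller than n_muscles")
  if (n_synergies_true > n_muscles - n_unmeasured)
    stop("n_synergies_true cannot exceed the number of measured muscles")
  structure(list(n_muscles = as.integer(n_muscles),
                 n_unmeasured = as.integer(n_unmeasured),
                 n_synergies_true = as.integer(n_synergies_true),
                 n_trials_per_speed = as.integer(n_trials_per_speed),
                 speeds = speeds,
                 noise_sd_excitation = noise_sd_excitation,
                 noise_sd_moment = noise_sd_moment,
                 weight_variability = weight_variability,
                 shape_jitter_amp = shape_jitter_amp,
                 shape_jitter_phase = shape_jitter_phase,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# 12 reference muscles over hip/knee/ankle flexion-type DOFs. rho > 0:
# the muscle shortens as the angle increases (flexor-like path); the first
# two are the deep hip flexors used for hold-out experiments.
.fixture_muscle_table <- function(n_muscles) {
  base <- list(
    # the two deep hip flexors differ in their frontal-plane action
    # (opposite-signed hip add/abduction arms) and in sagittal moment-arm
    # phase, so their joint-moment signatures are linearly independent:
    # the SynX split between simultaneously held-out muscles is
    # identifiable only if the moments can tell them apart
    iliacus  = list(l0 = 0.22, rho = c(hip_fe = 0.035, hip_aa = 0.014),
                    phi = c(hip_fe = -0.15, hip_aa = 0.00)),
    psoas    = list(l0 = 0.27, rho = c(hip_fe = 0.030, hip_aa = -0.012),
                    phi = c(hip_fe = 0.55, hip_aa = 0.25)),
    glut_max = list(l0 = 0.25, rho = c(hip_fe = -0.040, hip_aa = -0.016),
                    phi = c(hip_fe = -0.10, hip_aa = -0.20)),
    rect_fem = list(l0 = 0.42, rho = c(hip_fe = 0.028, knee_fe = -0.038),
                    phi = c(hip_fe = 0.05, knee_fe = 0.10)),
    vas_med  = list(l0 = 0.30, rho = c(knee_fe = -0.042), phi = c(knee_fe = 0.00)),
    vas_lat  = list(l0 = 0.30, rho = c(knee_fe = -0.038), phi = c(knee_fe = 0.20)),
    ham_med  = list(l0 = 0.40, rho = c(hip_fe = -0.034, knee_fe = 0.030),
                    phi = c(hip_fe = 0.00, knee_fe = -0.10)),
    ham_lat  = list(l0 = 0.40, rho = c(hip_fe = -0.030, knee_fe = 0.028),
                    phi = c(hip_fe = 0.20, knee_fe = 0.05)),
    gas_med  = list(l0 = 0.39, rho = c(knee_fe = 0.020, ankle_pd = -0.045),
                    phi = c(knee_fe = 0.00, ankle_pd = 0.00)),
    soleus   = list(l0 = 0.31, rho = c(ankle_pd = -0.040), phi = c(ankle_pd = 0.10)),
    tib_ant  = list(l0 = 0.28, rho = c(ankle_pd = 0.037), phi = c(ankle_pd = 0.00)),
    per_long = list(l0 = 0.32, rho = c(ankle_pd = -0.030), phi = c(ankle_pd = -0.20))
  )
  if (n_muscles > length(base))
    stop("the planar fixture provides at most ", length(base), " muscles")
  base[seq_len(n_muscles)]
}

#' Planar-leg geometry fixture and nominal muscle-tendon parameters
#'
#' An analytic sinusoidal-path geometry over hip (two DOFs), knee and
#' ankle with up to 12 muscles (including two deep hip flexors and antagonist
#' pairs at every joint), plus a nominal [muscle_params()] table with
#' physiological maximum isometric forces (340--1800 N), optimal fiber
#' lengths (0.05--0.12 m) and tendon slack lengths placed so that fibers
#' operate near optimal length over the gait angle range.
#'
#' @param n_muscles number of muscles (default 12, maximum 12).
#' @return list with `geometry` (a [planar_geometry()]) and `params`
#'   (nominal [muscle_params()]).
#' @export
planar_leg_fixture <- function(n_muscles = 12L) {
  tab <- .fixture_muscle_table(n_muscles)
  dofs <- c("hip_fe", "hip_aa", "knee_fe", "ankle_pd")
  geometry <- planar_geometry(tab, dofs)
  mus <- names(tab)
  n <- length(mus)
  fmax <- c(900, 800, 1800, 1100, 1400, 1300, 1000, 900, 1200, 1700, 700,
            500)[seq_len(n)]
  lo <- c(0.10, 0.11, 0.12, 0.09, 0.09, 0.09, 0.08, 0.08, 0.06, 0.05,
          0.07, 0.06)[seq_len(n)]
  alpha <- c(0.12, 0.10, 0.05, 0.08, 0.05, 0.05, 0.00, 0.00, 0.30, 0.45,
             0.08, 0.17)[seq_len(n)]
  # place slack length so the fiber sits slightly below optimal length at
  # the neutral pose (non-zero force-length slope over the motion)
  lmt0 <- muscle_tendon_lengths(geometry,
                                matrix(0, 1, length(dofs),
                                       dimnames = list(NULL, dofs)))
  ls <- as.numeric(lmt0) - 0.95 * lo
  params <- muscle_params(mus, semg = 0.9, d = 0.03, tau_act = 0.02,
                          c3 = 0.1, fmax = fmax, lo_nom = lo, ls_nom = ls,
                          alpha = alpha)
  list(geometry = geometry, params = params)
}

# Circular raised-cosine bump of unit peak at phase centre `cen` (cycle
# fraction) with full width `w`.
.raised_cosine <- function(phase, cen, w) {
  d <- (phase - cen) %% 1
  d <- pmin(d, 1 - d)
  ifelse(d < w / 2, 0.5 * (1 + cos(2 * pi * d / w)), 0)
}

# Smooth periodic joint-angle trajectories (rad) and velocities (rad/s)
# as functions of cycle phase; amplitude grows mildly with speed.
.joint_trajectories <- function(phase, tf, speed_gain) {
  two_pi <- 2 * pi
  # three harmonics per DOF: real gait kinematics carry substantial
  # higher-harmonic content, and the wider fiber-length excursions it
  # induces are what make the muscle-tendon length parameters
  # identifiable from moments
  harm <- function(off, a1, p1, a2, p2, a3, p3) {
    list(th = off + a1 * sin(two_pi * phase + p1) +
           a2 * sin(2 * two_pi * phase + p2) +
           a3 * sin(3 * two_pi * phase + p3),
         thd = (a1 * two_pi * cos(two_pi * phase + p1) +
                  a2 * 2 * two_pi * cos(2 * two_pi * phase + p2) +
                  a3 * 3 * two_pi * cos(3 * two_pi * phase + p3)) / tf)
  }
  hip <- harm(0.05, 0.35 * speed_gain, 2.6, 0.06, 1.0, 0.035, -0.7)
  haa <- harm(-0.02, 0.10 * speed_gain, 1.4, 0.03, -0.5, 0.02, 0.9)
  kne <- harm(0.45, 0.40 * speed_gain, -1.2, 0.10, 0.4, 0.05, 1.8)
  ank <- harm(0.02, 0.22 * speed_gain, 0.6, 0.06, -0.8, 0.04, 0.3)
  th <- cbind(hip_fe = hip$th, hip_aa = haa$th, knee_fe = kne$th,
              ankle_pd = ank$th)
  thd <- cbind(hip_fe = hip$thd, hip_aa = haa$thd, knee_fe = kne$thd,
               ankle_pd = ank$thd)
  list(theta = th, thetadot = thd)
}

#' Generate a synthetic gait dataset with known ground truth
#'
#' Muscle excitations are built as `W %*% H + mu` from smooth non-negative
#' synergy excitations (raised-cosine bumps at staggered gait phases with
#' distinct amplitudes, so the principal-component variance spectrum is
#' well separated) and non-negative sparse synergy weights whose
#' between-trial variability follows `weight_variability`. "Experimental"
#' joint moments are forward-computed through the planar fixture at the
#' true muscle-tendon parameters, then noise is added per the config.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `synthetic_dataset`: a list with `dataset` (a
#'   [gait_dataset()] with all muscles measured; see [holdout_muscles()]),
#'   `geometry`, `params_nominal`, `params_true`, `config`, and `truth`
#'   (per-trial generating synergy excitations `W`, per-group weights `H`
#'   and means `mu`, noiseless excitations and noiseless moments).
#' @export
generate_synthetic_gait <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  fix <- planar_leg_fixture(cfg$n_muscles)
  mus <- rownames(fix$params)
  n_pre <- 20L; n_cycle <- 101L
  p <- cfg$n_synergies_true
  n_trials <- cfg$n_trials_per_speed * length(cfg$speeds)

  # true muscle-tendon parameters: plausible perturbations of nominal
  params_true <- fix$params
  n <- length(mus)
  params_true$semg <- stats::runif(n, 0.75, 0.95)
  params_true$d <- stats::runif(n, 0.01, 0.05)
  params_true$tau_act <- stats::runif(n, 0.015, 0.035)
  params_true$c3 <- stats::runif(n, 0.05, 0.25)
  params_true$scale_lo <- stats::runif(n, 0.92, 1.08)
  params_true$scale_ls <- stats::runif(n, 0.98, 1.02)

  # synergy shapes: staggered centres with distinct widths/amplitudes so
  # the component variance spectrum is well separated but no component is
  # negligible (every one must matter for the 95% VAF bookkeeping)
  centres <- seq(0.05, 0.85, length.out = p)
  widths <- seq(0.24, 0.18, length.out = p)
  amps <- seq(1.0, 0.9, length.out = p)

  # non-negative sparse base weights: each muscle mainly loads on 1-2
  # synergies, assigned round-robin so every synergy is represented
  H_base <- matrix(0, p, cfg$n_muscles, dimnames = list(NULL, mus))
  for (j in seq_len(cfg$n_muscles)) {
    main <- (j - 1L) %% p + 1L
    H_base[main, j] <- stats::runif(1, 0.55, 0.9)
    extra <- sample(setdiff(seq_len(p), main), 1)
    H_base[extra, j] <- stats::runif(1, 0.1, 0.35)
  }
  mu_base <- stats::runif(cfg$n_muscles, 0.02, 0.05)
  names(mu_base) <- mus

  speed_of_trial <- rep(cfg$speeds, each = cfg$n_trials_per_speed)
  trial_ids <- sprintf("trial_%02d", seq_len(n_trials))

  # group-level true weights per the requested variability
  group_of <- switch(cfg$weight_variability,
                     trial = trial_ids,
                     speed = speed_of_trial,
                     subject = rep("subject", n_trials))
  H_true <- list(); mu_true <- list()
  for (g in unique(group_of)) {
    jit <- matrix(stats::runif(p * cfg$n_muscles, 0.85, 1.15), p)
    H_true[[g]] <- H_base * jit
    mu_true[[g]] <- mu_base * stats::runif(cfg$n_muscles, 0.9, 1.1)
  }

  phase_grid <- ((seq_len(n_pre + n_cycle) - n_pre - 1) / (n_cycle - 1))
  tf_base <- c(1.40, 1.15)[match(speed_of_trial, cfg$speeds)]

  # first pass: synergy excitations and noiseless muscle excitations
  W_list <- list(); exc_clean <- list()
  tf_trial <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    id <- trial_ids[i]
    tf_trial[i] <- tf_base[i] * stats::runif(1, 0.98, 1.02)
    # per-trial shape jitter: small phase and amplitude perturbations
    ph_jit <- stats::runif(p, -cfg$shape_jitter_phase,
                           cfg$shape_jitter_phase)
    amp_jit <- stats::runif(p, 1 - cfg$shape_jitter_amp,
                            1 + cfg$shape_jitter_amp)
    W <- sapply(seq_len(p), function(s)
      amps[s] * amp_jit[s] *
        .raised_cosine(phase_grid %% 1, centres[s] + ph_jit[s], widths[s]))
    g <- group_of[i]
    E0 <- W %*% H_true[[g]] +
      matrix(mu_true[[g]], nrow(W), cfg$n_muscles, byrow = TRUE)
    colnames(E0) <- mus
    W_list[[id]] <- W
    exc_clean[[id]] <- E0
  }

  # normalise each muscle to its maximum over all trials (exactly what
  # processed EMG looks like after max normalisation); per-channel scaling
  # preserves the rank-p structure about the mean
  chan_max <- Reduce(pmax, lapply(exc_clean, function(E) apply(E, 2L, max)))
  exc_clean <- lapply(exc_clean, function(E) sweep(E, 2L, chan_max, "/"))
  for (g in names(H_true)) {
    H_true[[g]] <- sweep(H_true[[g]], 2L, chan_max, "/")
    mu_true[[g]] <- mu_true[[g]] / chan_max
  }

  # second pass: trials with forward-computed "experimental" moments
  trials <- list(); M_clean <- list()
  for (i in seq_len(n_trials)) {
    id <- trial_ids[i]
    tf <- tf_trial[i]
    dt <- tf / (n_cycle - 1)
    time <- (seq_len(n_pre + n_cycle) - n_pre - 1) * dt
    E0 <- exc_clean[[id]]
    E <- E0
    if (cfg$noise_sd_excitation > 0) {
      E <- E + matrix(stats::rnorm(length(E), 0, cfg$noise_sd_excitation),
                      nrow(E))
      E[E < 0] <- 0
      E[E > 1] <- 1
      colnames(E) <- mus
    }
    speed_gain <- if (speed_of_trial[i] == cfg$speeds[1]) 1 else 1.18
    kin <- .joint_trajectories(phase_grid, tf, speed_gain)
    trial <- gait_trial(id, speed_of_trial[i], "right", time,
                        excitations = E, joint_angles = kin$theta,
                        joint_velocities = kin$thetadot,
                        id_moments = matrix(0, length(time),
                                            ncol(kin$theta),
                                            dimnames = list(NULL,
                                                            colnames(kin$theta))),
                        cycle_duration = tf)
    fwd <- forward_chain(trial, params_true, fix$geometry, excitations = E0)
    M <- fwd$M
    if (cfg$noise_sd_moment > 0)
      M <- M + matrix(stats::rnorm(length(M), 0, cfg$noise_sd_moment),
                      nrow(M), dimnames = dimnames(M))
    trial$id_moments <- M
    trials[[id]] <- trial
    M_clean[[id]] <- fwd$M
  }

  structure(
    list(dataset = gait_dataset(trials),
         geometry = fix$geometry,
         params_nominal = fix$params,
         params_true = params_true,
         config = cfg,
         unmeasured_candidates = mus[seq_len(cfg$n_unmeasured)],
         truth = list(W = W_list, H = H_true, mu = mu_true,
                      group_of_trial = stats::setNames(group_of, trial_ids),
                      excitations = exc_clean,
                      moments = M_clean)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> seed", x$config$seed, "\n")
  print(x$dataset)
  cat("  true synergies:", x$config$n_synergies_true,
      "| weight variability:", x$config$weight_variability, "\n")
  invisible(x)
}

#' Move muscles to the unmeasured set of a dataset
#'
#' Marks the named muscles as unmeasured; their excitation columns stay in
#' the trials (they are the ground truth for scoring) but are excluded
#' from [measured_excitations()] and hence from everything the calibration
#' sees.
#'
#' @param dataset a [gait_dataset()].
#' @param names muscle names to hold out; defaults of a
#'   [generate_synthetic_gait()] result use its designated candidates.
#' @return a new `gait_dataset`.
#' @export
holdout_muscles <- function(dataset, names) {
  if (inherits(dataset, "synthetic_dataset")) {
    if (missing(names)) names <- dataset$unmeasured_candidates
    dataset <- dataset$dataset
  }
  if (length(names) == 0) return(dataset)
  gait_dataset(dataset$trials,
               unmeasured_muscles = union(dataset$unmeasured_muscles, names))
}
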