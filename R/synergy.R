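# Muscle synergy analysis by PCA with trial-, speed- or subject-specific
# concatenation of the measured excitation matrices.

#' Concatenate measured excitations by weight-variability category
#'
#' Synergy vector weights can be assumed constant within a trial, within a
#' speed, or across the whole subject; each assumption dictates how the
#' measured-muscle excitation matrices are stacked before PCA:
#' * `"trial"` -- one matrix per trial (121 rows each);
#' * `"speed"` -- one matrix per speed, trials at that speed stacked in
#'   trial order (605 rows for 5 trials);
#' * `"subject"` -- a single matrix over all trials (1210 rows for 10).
#'
#' @param dataset a [gait_dataset()]; only measured muscles are used.
#' @param category `"trial"`, `"speed"` or `"subject"`.
#' @return named list of matrices (rows x measured muscles); each carries a
#'   `frame_partition` attribute mapping trial ids to row ranges.
#' @export
concatenate_excitations <- function(dataset,
                                    category = c("trial", "speed", "subject")) {
  category <- match.arg(category)
  ids <- names(dataset$trials)
  groups <- switch(category,
    trial = stats::setNames(as.list(ids), ids),
    speed = {
      sp <- vapply(dataset$trials, function(tr) tr$speed_label, character(1))
      lapply(stats::setNames(nm = dataset_speeds(dataset)),
             function(s) ids[sp == s])
    },
    subject = list(subject = ids))
  lapply(groups, function(members) {
    mats <- lapply(members, function(id) measured_excitations(dataset, id))
    nrows <- vapply(mats, nrow, integer(1))
    offs <- cumsum(c(0L, nrows[-length(nrows)]))
    partition <- stats::setNames(
      lapply(seq_along(members), function(i) offs[i] + seq_len(nrows[i])),
      members)
    out <- do.call(rbind, mats)
    attr(out, "frame_partition") <- partition
    out
  })
}

#' PCA decomposition of a measured excitation matrix
#'
#' Decomposes `E = Wm %*% Hm + mu_m + eps_m`, where `Wm` (frames x p) holds
#' the measured synergy excitations (principal-component scores), `Hm`
#' (p x muscles) the synergy vector weights (loadings), `mu_m` the column
#' means, and `eps_m` the part not captured by the first `p` components.
#' Components are ordered by decreasing explained variance, and each is
#' sign-flipped so its largest-magnitude loading is positive (PCA signs are
#' otherwise arbitrary).
#'
#' @param E matrix, frames x measured muscles.
#' @param p number of synergies, `1 <= p <= min(nrow - 1, ncol)`.
#' @return object of class `synergy_decomposition` with elements `Wm`, `Hm`,
#'   `mu`, `eps`, `p`, `sdev` (all component standard deviations) and the
#'   `frame_partition` attribute of `E` if present.
#' @export
pca_decompose <- function(E, p) {
  E <- as.matrix(E)
  n <- nrow(E); k <- ncol(E)
  pmax_ <- min(n - 1L, k)
  if (p < 1 || p > pmax_)
    stop("p must be between 1 and ", pmax_, ", got ", p)
  pc <- stats::prcomp(E, center = TRUE, scale. = FALSE)
  W <- pc$x[, seq_len(p), drop = FALSE]
  H <- t(pc$rotation[, seq_len(p), drop = FALSE])
  # fixed sign convention: largest-magnitude loading of each component > 0
  for (j in seq_len(p)) {
    i <- which.max(abs(H[j, ]))
    if (H[j, i] < 0) {
      H[j, ] <- -H[j, ]
      W[, j] <- -W[, j]
    }
  }
  mu <- matrix(pc$center, nrow = 1, dimnames = list(NULL, colnames(E)))
  recon <- W %*% H + matrix(mu, n, k, byrow = TRUE)
  structure(
    list(Wm = W, Hm = H, mu = mu, eps = E - recon, p = as.integer(p),
         sdev = pc$sdev,
         frame_partition = attr(E, "frame_partition")),
    class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat("<synergy_decomposition> p =", x$p, "synergies,",
      nrow(x$Wm), "frames x", ncol(x$Hm), "muscles\n")
  cat("  reconstruction VAF:",
      sprintf("%.2f%%", compute_vaf(x$Wm %*% x$Hm +
        matrix(x$mu, nrow(x$Wm), ncol(x$Hm), byrow = TRUE) + x$eps,
        x$Wm %*% x$Hm +
        matrix(x$mu, nrow(x$Wm), ncol(x$Hm), byrow = TRUE))), "\n")
  invisible(x)
}

#' Reconstruct the excitation matrix from a decomposition
#' @param dec a `synergy_decomposition`.
#' @param include_eps include the residual term (then the reconstruction is
#'   exact).
#' @return frames x muscles matrix.
#' @export
synergy_reconstruct <- function(dec, include_eps = FALSE) {
  out <- dec$Wm %*% dec$Hm +
    matrix(dec$mu, nrow(dec$Wm), ncol(dec$Hm), byrow = TRUE)
  if (include_eps) out <- out + dec$eps
  out
}

#' Variance accounted for (uncentred, pooled)
#'
#' `VAF = 100 * (1 - ||E - E_hat||_F^2 / ||E||_F^2)`, the muscle-synergy
#' convention (uncentred total variance, pooled over the matrix).
#'
#' @param E reference matrix.
#' @param E_hat reconstruction of the same shape.
#' @return percent, bounded above by 100.
#' @export
compute_vaf <- function(E, E_hat) {
  E <- as.matrix(E); E_hat <- as.matrix(E_hat)
  if (!all(dim(E) == dim(E_hat))) stop("shape mismatch")
  denom <- sum(E^2)
  if (denom == 0) stop("VAF undefined for an all-zero reference matrix")
  100 * (1 - sum((E - E_hat)^2) / denom)
}

#' Smallest number of synergies reaching a VAF threshold
#'
#' @param E matrix, frames x muscles.
#' @param threshold VAF threshold in percent, in (0, 100] (default 95).
#' @param p_range candidate synergy counts (default `1:min(n-1, k)`).
#' @return the minimal `p` with VAF >= threshold.
#' @export
select_num_synergies <- function(E, threshold = 95, p_range = NULL) {
  E <- as.matrix(E)
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]")
  pmax_ <- min(nrow(E) - 1L, ncol(E))
  if (is.null(p_range)) p_range <- seq_len(pmax_)
  p_range <- sort(p_range)
  best <- -Inf
  for (p in p_range) {
    dec <- pca_decompose(E, p)
    vaf <- compute_vaf(E, synergy_reconstruct(dec))
    if (vaf >= threshold) return(p)
    best <- max(best, vaf)
  }
  stop("no synergy count in range reaches VAF ", threshold,
       "%; best achieved ", sprintf("%.2f%%", best))
}

#' Per-category synergy decompositions of a dataset
#'
#' Runs [concatenate_excitations()] then [pca_decompose()] for one category.
#'
#' @param dataset a [gait_dataset()].
#' @param p number of synergies.
#' @param category concatenation category.
#' @return named list of `synergy_decomposition` objects (one per group).
#' @export
decompose_dataset <- function(dataset, p,
                              category = c("trial", "speed", "subject")) {
  category <- match.arg(category)
  mats <- concatenate_excitations(dataset, category)
  out <- lapply(mats, pca_decompose, p = p)
  attr(out, "category") <- category
  out
}

# Rows of the group-level Wm belonging to one trial, as a frames x p
# matrix. With normalize = TRUE each score column is divided by its
# group-level standard deviation (floored for degenerate components), so
# weights attached to different components act on a common scale; this is
# the parameterisation the calibration optimises over.
.wm_for_trial <- function(decs, trial_id, normalize = FALSE) {
  for (g in names(decs)) {
    part <- decs[[g]]$frame_partition
    if (!is.null(part[[trial_id]])) {
      W <- decs[[g]]$Wm[part[[trial_id]], , drop = FALSE]
      if (normalize) {
        s <- decs[[g]]$sdev[seq_len(ncol(W))]
        W <- sweep(W, 2L, pmax(s, 1e-6 * s[1]), "/")
      }
      return(list(group = g, Wm = W))
    }
  }
  stop("trial ", trial_id, " not found in any decomposition group")
}
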