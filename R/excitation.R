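# SynX core: unmeasured and residual muscle excitations as linear
# combinations of measured synergy excitations.

#' Construct excitations from synergy excitations and weights
#'
#' `construct_unmeasured()` builds unmeasured muscle excitations
#' `eSynX = Wm %*% H + mu`; `construct_residual()` builds residual
#' excitations `eres = Wm %*% H + mu` for the measured muscles. Values are
#' sign-unrestricted at this stage: residual excitations are allowed to be
#' negative, and clamping to `[0, 1]` happens only at the muscle-model
#' boundary (see [forward_chain()]).
#'
#' @param Wm frames x p measured synergy excitations (scores for the weight
#'   set's own group and category).
#' @param H p x q synergy vector weights.
#' @param mu length-q (or 1 x q) average values.
#' @return frames x q matrix.
#' @export
construct_unmeasured <- function(Wm, H, mu) {
  Wm <- as.matrix(Wm); H <- as.matrix(H)
  mu <- as.numeric(mu)
  if (ncol(Wm) != nrow(H))
    stop("dimension mismatch: Wm has ", ncol(Wm), " synergies but H has ",
         nrow(H), " rows")
  if (length(mu) != ncol(H))
    stop("mu must have one entry per constructed excitation")
  Wm %*% H + matrix(mu, nrow(Wm), ncol(H), byrow = TRUE,
                    dimnames = list(NULL, colnames(H)))
}

#' @rdname construct_unmeasured
#' @export
construct_residual <- construct_unmeasured

#' Add residual excitations to measured excitations
#'
#' @param em frames x q measured muscle excitations.
#' @param eres frames x q residual excitations (may be negative).
#' @return `em + eres` elementwise.
#' @export
add_residuals <- function(em, eres) {
  em <- as.matrix(em); eres <- as.matrix(eres)
  if (!all(dim(em) == dim(eres))) stop("shape mismatch between em and eres")
  em + eres
}

#' Weight sets for one category
#'
#' Bundles one `(H, mu)` pair per group: one per trial for trial-specific
#' weights, one per speed for speed-specific, a single set for
#' subject-specific.
#'
#' @param H named list of p x q weight matrices keyed by group id.
#' @param mu named list of length-q average-value vectors, same keys.
#' @param category `"trial"`, `"speed"` or `"subject"`.
#' @return object of class `synx_weights`.
#' @export
synx_weights <- function(H, mu, category = c("trial", "speed", "subject")) {
  category <- match.arg(category)
  if (!identical(names(H), names(mu)))
    stop("H and mu must share group names")
  dims <- vapply(H, dim, integer(2))
  if (length(H) > 1 && (any(dims[1, ] != dims[1, 1]) ||
                        any(dims[2, ] != dims[2, 1])))
    stop("all weight sets must share dimensions")
  structure(list(H = lapply(H, as.matrix),
                 mu = lapply(mu, as.numeric),
                 category = category),
            class = "synx_weights")
}

# Group id owning a trial under a category.
.group_of_trial <- function(dataset, trial_id,
                            category = c("trial", "speed", "subject")) {
  category <- match.arg(category)
  switch(category,
         trial = trial_id,
         speed = dataset$trials[[trial_id]]$speed_label,
         subject = "subject")
}

#' Construct per-trial excitations for a whole dataset
#'
#' For each trial, selects the `Wm` block of the decomposition group that
#' owns the trial under the weights' category (the synergy excitations used
#' for reconstruction are always the ones extracted under the same
#' category), then applies that group's weight set.
#'
#' @param dataset a [gait_dataset()].
#' @param decs decompositions from [decompose_dataset()] with the same
#'   category as `weights`.
#' @param weights a [synx_weights()].
#' @return named list of frames x q matrices, one per trial.
#' @export
construct_for_dataset <- function(dataset, decs, weights) {
  if (!identical(attr(decs, "category"), weights$category))
    stop("decomposition category (", attr(decs, "category"),
         ") does not match weights category (", weights$category, ")")
  out <- lapply(names(dataset$trials), function(id) {
    g <- .group_of_trial(dataset, id, weights$category)
    if (is.null(weights$H[[g]]))
      stop("no weight set for group ", g)
    wm <- .wm_for_trial(decs, id)
    construct_unmeasured(wm$Wm, weights$H[[g]], weights$mu[[g]])
  })
  stats::setNames(out, names(dataset$trials))
}

#' Flat design-vector layout for SynX and residual weights
#'
#' Defines a bijection between the flat optimisation vector and the
#' `(H, mu)` weight sets on both sides. Each side contributes
#' `(p + 1) * q * n_groups` entries (`p` weights plus one average value per
#' constructed excitation per group).
#'
#' @param p number of synergies.
#' @param q_unmeasured number of unmeasured muscles (0 to drop the side).
#' @param q_measured number of measured muscles (0 to drop the residual
#'   side).
#' @param groups_unmeasured,groups_residual character vectors of group ids
#'   (trial ids, speed labels, or `"subject"`).
#' @param category_unmeasured,category_residual categories of the two sides.
#' @return object of class `weight_layout` with `$length` and
#'   pack/unpack via [pack_weights()] / [unpack_weights()].
#' @export
weight_layout <- function(p, q_unmeasured, q_measured,
                          groups_unmeasured = character(),
                          groups_residual = character(),
                          category_unmeasured = "trial",
                          category_residual = "trial") {
  q_unmeasured <- as.integer(q_unmeasured)
  q_measured <- as.integer(q_measured)
  n_unm <- (as.integer(p) + 1L) * q_unmeasured * length(groups_unmeasured)
  n_res <- (as.integer(p) + 1L) * q_measured * length(groups_residual)
  structure(list(p = as.integer(p),
                 q_unmeasured = as.integer(q_unmeasured),
                 q_measured = as.integer(q_measured),
                 groups_unmeasured = groups_unmeasured,
                 groups_residual = groups_residual,
                 category_unmeasured = category_unmeasured,
                 category_residual = category_residual,
                 n_unmeasured = as.integer(n_unm),
                 n_residual = as.integer(n_res),
                 length = as.integer(n_unm + n_res)),
            class = "weight_layout")
}

# One side's sets <-> flat segment. Per group: H column-major, then mu.
.pack_side <- function(sets) {
  unlist(lapply(names(sets$H), function(g)
    c(as.numeric(sets$H[[g]]), sets$mu[[g]])), use.names = FALSE)
}

.unpack_side <- function(x, p, q, groups, category) {
  per <- (p + 1L) * q
  H <- list(); mu <- list()
  for (i in seq_along(groups)) {
    seg <- x[(i - 1L) * per + seq_len(per)]
    H[[groups[i]]] <- matrix(seg[seq_len(p * q)], p, q)
    mu[[groups[i]]] <- seg[p * q + seq_len(q)]
  }
  synx_weights(H, mu, category)
}

#' @rdname weight_layout
#' @param layout a `weight_layout`.
#' @param unmeasured,residual [synx_weights()] for the two sides (`NULL`
#'   when the side has zero length).
#' @export
pack_weights <- function(layout, unmeasured = NULL, residual = NULL) {
  x <- numeric(0)
  if (layout$n_unmeasured > 0) x <- c(x, .pack_side(unmeasured))
  if (layout$n_residual > 0) x <- c(x, .pack_side(residual))
  if (length(x) != layout$length)
    stop("packed vector length ", length(x), " does not match layout length ",
         layout$length)
  x
}

#' @rdname weight_layout
#' @param x flat numeric vector of length `layout$length`.
#' @export
unpack_weights <- function(layout, x) {
  if (length(x) != layout$length)
    stop("expected vector of length ", layout$length, ", got ", length(x))
  out <- list(unmeasured = NULL, residual = NULL)
  if (layout$n_unmeasured > 0)
    out$unmeasured <- .unpack_side(x[seq_len(layout$n_unmeasured)],
                                   layout$p, layout$q_unmeasured,
                                   layout$groups_unmeasured,
                                   layout$category_unmeasured)
  if (layout$n_residual > 0)
    out$residual <- .unpack_side(x[layout$n_unmeasured + seq_len(layout$n_residual)],
                                 layout$p, layout$q_measured,
                                 layout$groups_residual,
                                 layout$category_residual)
  out
}
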