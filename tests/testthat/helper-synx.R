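# Shared test fixtures and independent oracles.

# Brute-force one-sided Jacobi SVD: orthogonalise column pairs of A until
# convergence. Independent of svd()/eigen()/prcomp(); used as the oracle
# for the PCA decomposition.
jacobi_svd <- function(A, tol = 1e-12, max_sweeps = 60) {
  A <- as.matrix(A)
  k <- ncol(A)
  V <- diag(k)
  for (sweep in seq_len(max_sweeps)) {
    off <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        alpha <- sum(A[, p]^2)
        beta <- sum(A[, q]^2)
        gamma <- sum(A[, p] * A[, q])
        off <- max(off, abs(gamma) / sqrt(alpha * beta + 1e-300))
        if (abs(gamma) < tol * sqrt(alpha * beta)) next
        zeta <- (beta - alpha) / (2 * gamma)
        t <- sign(zeta) / (abs(zeta) + sqrt(1 + zeta^2))
        cs <- 1 / sqrt(1 + t^2)
        sn <- cs * t
        Ap <- A[, p]
        A[, p] <- cs * Ap - sn * A[, q]
        A[, q] <- sn * Ap + cs * A[, q]
        Vp <- V[, p]
        V[, p] <- cs * Vp - sn * V[, q]
        V[, q] <- sn * Vp + cs * V[, q]
      }
    }
    if (off < tol) break
  }
  d <- sqrt(colSums(A^2))
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]
  U <- sweep(A[, ord, drop = FALSE], 2L, pmax(d, 1e-300), "/")
  list(d = d, u = U, v = V[, ord, drop = FALSE])
}

# Deterministic small excitation matrix with named columns.
seeded_matrix <- function(n, k, seed = 42, names_prefix = "m") {
  set.seed(seed)
  matrix(stats::runif(n * k), n, k,
         dimnames = list(NULL, paste0(names_prefix, seq_len(k))))
}

# A minimal valid 121-frame gait trial with the given number of muscles
# and DOFs and smooth contents.
toy_trial <- function(id = "t1", n_mus = 3, n_dof = 2,
                      speed = "self-selected", tf = 1.2) {
  n <- 121L
  time <- (seq_len(n) - 21) * tf / 100
  ph <- (seq_len(n) - 21) / 100
  exc <- sapply(seq_len(n_mus), function(j)
    0.1 + 0.4 * (1 + sin(2 * pi * ph + j)) / 2)
  colnames(exc) <- paste0("mus", seq_len(n_mus))
  th <- sapply(seq_len(n_dof), function(j) 0.3 * sin(2 * pi * ph + j / 2))
  thd <- sapply(seq_len(n_dof), function(j)
    0.3 * 2 * pi / tf * cos(2 * pi * ph + j / 2))
  colnames(th) <- colnames(thd) <- paste0("dof", seq_len(n_dof))
  mom <- matrix(rnorm(n * n_dof, sd = 5), n,
                dimnames = list(NULL, colnames(th)))
  gait_trial(id, speed, "right", time, exc, th, thd, mom, tf)
}

# Small noiseless synthetic dataset reused across tests (cached).
.synx_test_env <- new.env(parent = emptyenv())
cached_synthetic <- function(seed = 7, ...) {
  key <- paste0("syn_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.synx_test_env[[key]]))
    .synx_test_env[[key]] <-
      generate_synthetic_gait(synthetic_config(seed = seed, ...))
  .synx_test_env[[key]]
}
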