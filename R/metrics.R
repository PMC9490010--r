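# Evaluation metrics: Pearson r with correlation-strength categories,
# RMSE, MAE, and tabular comparison reports between two model runs.

#' Pearson correlation with strength category
#'
#' Categories follow the convention: weak (r < 0.35), moderate
#' (0.35 <= r <= 0.67), strong (0.67 < r <= 0.9), very strong (r > 0.9);
#' boundaries are assigned per the left-open interval notation.
#'
#' @param a,b numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r` and `category`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3) stop("need at least 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson r is undefined for a zero-variance series")
  r <- stats::cor(a, b)
  list(r = r, category = correlation_category(r))
}

#' @rdname pearson_r
#' @param r correlation value(s) in `[-1, 1]`.
#' @export
correlation_category <- function(r) {
  ifelse(r < 0.35, "weak",
         ifelse(r <= 0.67, "moderate",
                ifelse(r <= 0.9, "strong", "very strong")))
}

#' Root-mean-square and mean-absolute error
#' @param a,b numeric vectors/matrices of equal shape.
#' @return a single number.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("shape mismatch")
  if (length(a) == 0) stop("empty input")
  sqrt(mean((a - b)^2))
}

#' @rdname rmse
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stop("shape mismatch")
  if (length(a) == 0) stop("empty input")
  mean(abs(a - b))
}

#' Compare two runs' time series item by item
#'
#' Builds a long-format report comparing matched per-trial series (one
#' column per muscle or DOF) between two runs: Pearson r with its strength
#' category, RMSE and MAE per item and trial, plus across-trial aggregate
#' rows (mean and sd).
#'
#' @param run_a,run_b named lists of trials; each trial is a frames x items
#'   matrix with identical column names across runs.
#' @param scope label recorded in the report (e.g. `"excitations"`,
#'   `"activations"`, `"forces"`, `"moments"`).
#' @return data.frame of class `comparison_report`.
#' @export
build_report <- function(run_a, run_b, scope = "moments") {
  if (!identical(names(run_a), names(run_b)))
    stop("runs must cover the same trials")
  rows <- list()
  for (id in names(run_a)) {
    A <- as.matrix(run_a[[id]]); B <- as.matrix(run_b[[id]])
    missing <- setdiff(colnames(A), colnames(B))
    if (length(missing))
      stop("run_b is missing item(s): ", paste(missing, collapse = ", "))
    B <- B[, colnames(A), drop = FALSE]
    if (nrow(A) != nrow(B)) stop("frame mismatch in trial ", id)
    for (it in colnames(A)) {
      r <- if (stats::sd(A[, it]) > 0 && stats::sd(B[, it]) > 0)
        stats::cor(A[, it], B[, it]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, trial = id, item = it, r = r,
        r_category = if (is.na(r)) NA_character_ else correlation_category(r),
        rmse = rmse(A[, it], B[, it]), mae = mae(A[, it], B[, it]))
    }
  }
  rep_ <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(rep_, rep_$item), function(d)
    data.frame(scope = scope, trial = "(mean)", item = d$item[1],
               r = mean(d$r), r_category = correlation_category(mean(d$r)),
               rmse = mean(d$rmse), mae = mean(d$mae))))
  out <- rbind(rep_, agg)
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}
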