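#' Matthews correlation coefficient
#'
#' Balanced classification metric in `[-1, 1]`: `+1` for perfect predictions,
#' `0` (by the zero-denominator convention) for a constant predictor.
#' Multiclass inputs use the generalized covariance-based formulation
#' `(c s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' over the confusion matrix, which reduces to the binary contingency formula
#' for two classes.
#'
#' @param y_true,y_pred vectors of class labels (any atomic type), equal
#'   length, at least one sample.
#' @return scalar in `[-1, 1]`.
#' @export
matthews_cc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (length(y_true) == 0L) stop("need at least one sample", call. = FALSE)
  lev <- sort(unique(c(y_true, y_pred)))
  t_f <- factor(y_true, levels = lev)
  p_f <- factor(y_pred, levels = lev)
  cm <- table(t_f, p_f)
  c_sum <- sum(diag(cm))
  s <- sum(cm)
  pk <- colSums(cm)   # predicted per class
  tk <- rowSums(cm)   # true per class
  num <- c_sum * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Regression metrics
#'
#' MAE, RMSE and the coefficient of determination `R^2 = 1 - SSE/SST`. A
#' constant `y_true` makes `R^2` undefined; it is reported as `NaN` with a
#' warning.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return named list with `mae`, `rmse`, `r2`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  err <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- if (sst == 0) {
    warning("constant y_true: R^2 is undefined")
    NaN
  } else 1 - sum(err^2) / sst
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r2 = r2)
}

#' Gini coefficient of a nonnegative score vector
#'
#' Inequality measure `sum_ij |x_i - x_j| / (2 n^2 mean(x))`: `0` for a
#' uniform vector, `(n - 1) / n` for a one-hot vector (approaching 1, maximal
#' inequality, as `n` grows). Used to summarize how concentrated a layer's
#' attention scores are.
#'
#' @param scores nonempty, nonnegative, not all zero.
#' @return scalar in `[0, 1)`.
#' @export
gini <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (any(scores < 0)) stop("scores must be nonnegative", call. = FALSE)
  if (all(scores == 0))
    stop("all-zero score vector: Gini undefined", call. = FALSE)
  n <- length(scores)
  x <- sort(scores)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  s <- sum((2 * seq_len(n) - n - 1) * x)
  s / (n^2 * mean(x))
}
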