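# Reliability statistics: ICC(2,1) absolute agreement with its exact F-based
# confidence interval, and RMS-SD precision.

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Mean squares from the two-way crossed ANOVA decomposition (subjects MSR,
#' raters MSC, residual MSE), then
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The confidence interval is the exact F-based construction for this form:
#' with `a = k*icc/(n(1-icc))` and `b = 1 + k*icc*(n-1)/(n(1-icc))`, the
#' denominator degrees of freedom are
#' `v = (a MSC + b MSE)^2 / ((a MSC)^2/(k-1) + (b MSE)^2/((n-1)(k-1)))`
#' (Satterthwaite), and with `FL = qf(1-alpha/2; n-1, v)`,
#' `FU = qf(1-alpha/2; v, n-1)`:
#' `lower = n(MSR - FL*MSE) / (FL(k*MSC + (kn-k-n) MSE) + n MSR)`,
#' `upper = n(FU*MSR - MSE) / (k*MSC + (kn-k-n) MSE + n FU MSR)`.
#'
#' @param table a subjects-by-raters matrix, or a tidy data frame with
#'   columns `subject`, `rater`, `value` (complete cells).
#' @param conf_level confidence level (0.95).
#' @return an object of class `icc_fit`: list with `icc`, `ci`
#'   (length-2), `ms` (MSR, MSC, MSE), `n`, `k`, `conf_level`.
#' @examples
#' m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' icc_2_1(m)$icc
#' @export
icc_2_1 <- function(table, conf_level = 0.95) {
  m <- if (is.matrix(table)) table else rater_matrix(table)
  if (anyNA(m)) stop("icc_2_1: missing cells are not allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("icc_2_1: need at least 2 subjects and 2 raters")
  grand <- mean(m)
  if (sum((m - grand)^2) < 1e-300)
    stop("icc_2_1: zero total variance, ICC undefined")
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= 0) {
    ci <- c(icc, icc)                   # degenerate: perfect agreement
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci = ci, ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement, single measurement\n  %d subjects x %d raters\n  ICC = %.3f, %d%% CI (%.3f to %.3f)\n",
              x$n, x$k, x$icc, round(100 * x$conf_level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' RMS-SD measurement precision
#'
#' Root mean square of the per-subject standard deviations across repeated
#' measurements: `RMS-SD = sqrt(sum(SD^2) / N)` with sample SDs (n-1
#' denominator). For intra-rater precision the repeats are the sessions of
#' one rater; for inter-rater precision the repeats are the values of a rater
#' pair.
#'
#' @param table a subjects-by-repeats numeric matrix, or a tidy data frame
#'   with columns `subject`, `value` and a repeat identifier named by
#'   `repeat_col` ("rater" for inter-, "session" for intra-rater precision).
#' @param mode "inter" or "intra"; only used to pick the default
#'   `repeat_col` for data-frame input.
#' @param repeat_col column defining repeats (data-frame input).
#' @param raters optional subset of repeat levels (e.g. a rater pair).
#' @return the RMS-SD (mm, scalar) with attribute `per_subject_sd`.
#' @examples
#' rms_sd(rbind(c(0, 3 * sqrt(2)), c(0, 4 * sqrt(2))))  # sqrt((9+16)/2)
#' @export
rms_sd <- function(table, mode = c("inter", "intra"), repeat_col = NULL,
                   raters = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(table)) {
    m <- table
  } else {
    repeat_col <- repeat_col %||% if (mode == "inter") "rater" else "session"
    stopifnot(all(c("subject", repeat_col, "value") %in% names(table)))
    tb <- table
    if (!is.null(raters)) tb <- tb[tb[[repeat_col]] %in% raters, , drop = FALSE]
    tb$rater <- tb[[repeat_col]]
    m <- rater_matrix(tb[c("subject", "rater", "value")])
  }
  if (!is.null(raters) && is.matrix(table)) m <- m[, raters, drop = FALSE]
  if (ncol(m) < 2) stop("rms_sd: need at least 2 repeats per subject")
  sds <- apply(m, 1, stats::sd)
  out <- sqrt(mean(sds^2))
  attr(out, "per_subject_sd") <- sds
  out
}
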