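# Cohort statistics: ANCOVA for sex differences with body height as
# covariate, and paired t tests between imaging modalities. Both are computed
# from explicit normal-equation / t formulas; base model fitters serve only
# as independent cross-checks in the test suite.

#' ANCOVA for a sex difference, adjusting for body height
#'
#' Least-squares fit of `value ~ sex + height`; the sex effect is tested by
#' the extra-sum-of-squares F test against the height-only model, and
#' sex-adjusted means are reported at the grand-mean height.
#'
#' @param cohort data frame with one row per subject.
#' @param parameter name of the value column (default "value").
#' @param sex_col,height_col column names; `sex` may be any two-level coding
#'   (factor, character or 0/1), `height` in metres.
#' @return an `ancova_fit`: list with `F`, `p`, `df` (1, n-3),
#'   `sex_effect` (second level minus first), `height_slope`,
#'   `adjusted_means` (tibble), `n`.
#' @examples
#' ch <- data.frame(value = c(5, 6, 7, 8), sex = c("F", "F", "M", "M"),
#'                  height = c(1.6, 1.62, 1.75, 1.8))
#' ancova_sex(ch)$p
#' @export
ancova_sex <- function(cohort, parameter = "value", sex_col = "sex",
                       height_col = "height") {
  stopifnot(all(c(parameter, sex_col, height_col) %in% names(cohort)))
  y <- as.numeric(cohort[[parameter]])
  sex <- factor(cohort[[sex_col]])
  hgt <- as.numeric(cohort[[height_col]])
  if (nlevels(sex) != 2) stop("ancova_sex: both sexes must be present")
  if (any(hgt <= 0)) stop("ancova_sex: heights must be positive")
  n <- length(y)
  if (n < 4) stop("ancova_sex: need at least 4 subjects")
  if (stats::var(hgt) < 1e-12)
    stop("ancova_sex: rank deficiency, covariate 'height' is constant")
  s <- as.numeric(sex) - 1            # 0/1 indicator, second level = 1
  X <- cbind(1, s, hgt)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("ancova_sex: rank deficiency, 'sex' is collinear with 'height'")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss_full <- sum(res^2)
  X0 <- cbind(1, hgt)
  res0 <- y - X0 %*% qr.coef(qr(X0), y)
  rss_red <- sum(res0^2)
  df2 <- n - 3
  Fval <- max(0, (rss_red - rss_full)) / (rss_full / df2)
  p <- stats::pf(Fval, 1, df2, lower.tail = FALSE)
  hbar <- mean(hgt)
  adj <- tibble::tibble(
    sex = levels(sex),
    adjusted_mean = unname(c(beta[1] + beta[3] * hbar,
                             beta[1] + beta[2] + beta[3] * hbar)))
  structure(list(F = Fval, p = p, df = c(1, df2),
                 sex_effect = unname(beta[2]), height_slope = unname(beta[3]),
                 adjusted_means = adj, n = n, parameter = parameter),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA (%s ~ sex + height), n = %d\n  sex effect %.3f mm, F(%d, %d) = %.3f, p = %.4g\n",
              x$parameter, x$n, x$sex_effect, x$df[1], x$df[2], x$F, x$p))
  print(x$adjusted_means)
  invisible(x)
}

#' Paired t test between two measurement series
#'
#' Classic paired t on the differences with a two-sided p value. A
#' zero-variance difference vector is reported as exact equality (t = 0,
#' p = 1) or as an exactly constant offset (p = 0) rather than failing.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return a `paired_t_fit`: list with `t`, `p`, `df`, `mean_diff`, `n`,
#'   `exact` (TRUE when the differences had zero variance).
#' @examples
#' paired_t(c(1, 2, 3), c(1, 2, 3))$p  # 1
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd < 1e-300) {
    if (abs(md) < 1e-300) {
      out <- list(t = 0, p = 1, df = n - 1, mean_diff = 0, n = n, exact = TRUE)
    } else {
      out <- list(t = sign(md) * Inf, p = 0, df = n - 1, mean_diff = md,
                  n = n, exact = TRUE)
    }
  } else {
    t <- md / (sdd / sqrt(n))
    out <- list(t = t, p = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
                mean_diff = md, n = n, exact = FALSE)
  }
  structure(out, class = "paired_t_fit")
}

#' @export
print.paired_t_fit <- function(x, ...) {
  cat(sprintf("paired t: t(%d) = %.3f, p = %.4g, mean difference %.4f%s\n",
              x$df, x$t, x$p, x$mean_diff,
              if (x$exact) " (zero-variance differences)" else ""))
  invisible(x)
}

#' Modality comparison table from a cohort of measurement records
#'
#' Pairs the per-subject values of a parameter across two modalities and runs
#' [paired_t()], mirroring the modality-comparison analysis.
#'
#' @param records tibble of measurement records (rows per subject x
#'   modality).
#' @param parameter column to compare (e.g. "TCS_A"); for the
#'   CT-vs-radiograph contrast use `parameter_y` for the second modality's
#'   column (e.g. TCS_P vs TCS).
#' @param modalities length-2 character, the two modalities.
#' @param parameter_y optional column name in the second modality.
#' @return tibble with the paired-t results.
#' @export
compare_modalities <- function(records, parameter,
                               modalities = c("3-D", "2-D axial"),
                               parameter_y = parameter) {
  a <- records[records$modality == modalities[1], c("subject", parameter)]
  b <- records[records$modality == modalities[2], c("subject", parameter_y)]
  mg <- merge(a, b, by = "subject", suffixes = c("_x", "_y"))
  cx <- if (parameter == parameter_y) paste0(parameter, "_x") else parameter
  cy <- if (parameter == parameter_y) paste0(parameter, "_y") else parameter_y
  if (nrow(mg) < 2)
    return(tibble::tibble(parameter = parameter, modality_x = modalities[1],
                          modality_y = modalities[2], n = nrow(mg),
                          t = NA_real_, p = NA_real_, mean_diff = NA_real_))
  ft <- paired_t(mg[[cx]], mg[[cy]])
  tibble::tibble(parameter = parameter, modality_x = modalities[1],
                 modality_y = modalities[2], n = ft$n, t = ft$t, p = ft$p,
                 mean_diff = ft$mean_diff)
}
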