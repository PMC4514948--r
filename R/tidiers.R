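# broom-style tidiers for the fitted statistics objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname icc_2_1
#' @param x an `icc_fit`.
#' @param ... unused.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "ICC(2,1)", estimate = x$icc,
                 conf.low = x$ci[1], conf.high = x$ci[2],
                 conf.level = x$conf_level)
}

#' @rdname icc_2_1
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 msr = unname(x$ms["MSR"]), msc = unname(x$ms["MSC"]),
                 mse = unname(x$ms["MSE"]), n = x$n, k = x$k)
}

#' @rdname ancova_sex
#' @param x an `ancova_fit`.
#' @param ... unused.
#' @export
tidy.ancova_fit <- function(x, ...) {
  tibble::tibble(term = c("sex", "height"),
                 estimate = c(x$sex_effect, x$height_slope),
                 statistic = c(x$F, NA_real_),
                 p.value = c(x$p, NA_real_))
}

#' @rdname ancova_sex
#' @export
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p, df = x$df[1],
                 df.residual = x$df[2], nobs = x$n)
}

#' @rdname paired_t
#' @param x a `paired_t_fit`.
#' @param ... unused.
#' @export
tidy.paired_t_fit <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t,
                 p.value = x$p, parameter = x$df, method = "paired t")
}
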