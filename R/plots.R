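# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a planar contour
#'
#' @param object a `contour` from [slice_contours()].
#' @param ... further contours to overlay.
#' @return a ggplot.
#' @export
autoplot.contour <- function(object, ...) {
  cts <- c(list(object), Filter(function(x) inherits(x, "contour"), list(...)))
  df <- dplyr::bind_rows(lapply(seq_along(cts), function(i) {
    ct <- cts[[i]]
    uv <- rbind(ct$uv, ct$uv[1, ])
    tibble::tibble(u = uv[, 1], v = uv[, 2],
                   bone = if (nzchar(ct$label)) ct$label else paste0("contour", i))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, colour = .data$bone)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "anterior (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the measurement-plane landmarks on the plane-Y section
#'
#' @param landmarks a `landmark_set` from [locate_landmarks()].
#' @param contours optional list of contours to draw beneath the landmarks.
#' @return a ggplot.
#' @export
plot_landmarks <- function(landmarks, contours = NULL) {
  lk <- landmarks$uv
  pts <- tibble::tibble(name = names(lk),
                        u = vapply(lk, `[`, 0, 1),
                        v = vapply(lk, `[`, 0, 2))
  p <- ggplot2::ggplot()
  if (!is.null(contours)) {
    df <- dplyr::bind_rows(lapply(contours, function(ct) {
      uv <- rbind(ct$uv, ct$uv[1, ])
      tibble::tibble(u = uv[, 1], v = uv[, 2], bone = ct$label)
    }))
    p <- p + ggplot2::geom_path(data = df,
      ggplot2::aes(x = .data$u, y = .data$v, group = .data$bone),
      colour = "grey50")
  }
  seg <- tibble::tibble(
    x = c(lk$A[1], lk$C[1], lk$A[1]), y = c(lk$A[2], lk$C[2], lk$A[2]),
    xend = c(lk$B[1], lk$D[1], lk$C[1]), yend = c(lk$B[2], lk$D[2], lk$C[2]),
    what = c("TCS-A", "TCS-P", "line AC"))
  p + ggplot2::geom_segment(data = seg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linetype = .data$what)) +
    ggplot2::geom_point(data = pts, ggplot2::aes(x = .data$u, y = .data$v),
                        colour = "red") +
    ggplot2::geom_text(data = pts,
      ggplot2::aes(x = .data$u, y = .data$v, label = .data$name),
      nudge_x = 0.8, nudge_y = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "anterior (mm)", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an AP silhouette
#'
#' @param object an `ap_silhouette` from [project_ap()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ap_silhouette <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$bones), function(nm) {
    tb <- object$bones[[nm]]
    tibble::tibble(bone = nm, z = tb$z, x_min = tb$x_min, x_max = tb$x_max)
  }))
  df <- df[is.finite(df$x_min) & is.finite(df$x_max), ]
  ggplot2::ggplot(df, ggplot2::aes(y = .data$z, xmin = .data$x_min,
                                   xmax = .data$x_max, fill = .data$bone)) +
    ggplot2::geom_ribbon(alpha = 0.5, orientation = "y") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "height (mm)", fill = NULL,
                  title = "Simulated AP projection") +
    ggplot2::theme_minimal()
}

#' Plot the parameter distributions of a cohort run
#'
#' @param object a `syndesmo_run` from [run_pipeline()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.syndesmo_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cohort,
                              cols = c("XY", "TCS_A", "TCS_P", "IFD", "IFH"),
                              names_to = "parameter", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sex, y = .data$mm,
                                     fill = .data$sex)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mm") +
    ggplot2::theme_minimal()
}
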