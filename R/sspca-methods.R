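#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an ssPCA fit
#'
#' One row per retained component: the eigenvalue of the objective matrix and
#' whether the direction is degenerate (eigenvalue below the fit's `eig_tol`).
#'
#' @param x Fitted `"sspca"` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `eigenvalue`, `degenerate`.
#' @method tidy sspca
#' @export
tidy.sspca <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    eigenvalue = x$eigenvalues,
    degenerate = x$eigenvalues < x$eig_tol
  )
}

#' One-row summary of an ssPCA fit
#'
#' @param x Fitted `"sspca"` object.
#' @param ... Unused.
#' @return A tibble with `n`, `n_clusters`, `k`, `lambda`, `objective` (sum of
#'   retained eigenvalues), and `n_degenerate`.
#' @method glance sspca
#' @export
glance.sspca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_clusters = length(x$class_order),
    k = x$k,
    lambda = x$lambda,
    objective = sum(x$eigenvalues),
    n_degenerate = x$n_degenerate
  )
}

#' Embedding coordinates as a tibble
#'
#' Returns the fitted embedding `Z = K_X W` with one row per cell: `cell_id`,
#' `dim1..dimk`, and `cluster`. Axes are named `dim`, not "PC", because for
#' `lambda > 0` the projection mixes variance with label dependence.
#'
#' @param x Fitted `"sspca"` object.
#' @param ... Unused.
#' @return A tibble with n rows.
#' @method augment sspca
#' @export
augment.sspca <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$embedding))
  dplyr::bind_cols(
    tibble::tibble(cell_id = x$cell_ids),
    out,
    tibble::tibble(cluster = factor(x$labels, levels = x$class_order))
  )
}

# Okabe-Ito colorblind-safe cycle, recycled for > 8 clusters.
palette_okabe_ito <- function(n) {
  base <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
            "#0072B2", "#D55E00", "#CC79A7", "#999999")
  rep_len(base, n)
}

#' Plot an ssPCA embedding
#'
#' Scatter plot of the first two embedding dimensions, colored by cluster
#' with a colorblind-safe palette.
#'
#' @param object Fitted `"sspca"` object.
#' @param dims Length-2 integer vector of dimensions to plot (default 1:2).
#' @param point_size Point size passed to `geom_point()`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sspca
#' @export
autoplot.sspca <- function(object, dims = c(1, 2), point_size = 1, ...) {
  stopifnot(length(dims) == 2, all(dims <= object$k))
  df <- augment(object)
  xcol <- paste0("dim", dims[1])
  ycol <- paste0("dim", dims[2])
  ggplot2::ggplot(df, ggplot2::aes(.data[[xcol]], .data[[ycol]], color = .data$cluster)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_color_manual(values = palette_okabe_ito(nlevels(df$cluster))) +
    ggplot2::labs(
      x = xcol, y = ycol, color = "cluster",
      title = sprintf("ssPCA embedding (lambda = %g)", object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.sspca <- function(x, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
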