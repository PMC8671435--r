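#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an admixture fit into one row per source
#'
#' @param x a `paleo_qpadm`
#' @param ... unused
#' @return tibble: `source`, `weight`, `std_error`
#' @export
tidy.paleo_qpadm <- function(x, ...) {
  tibble::tibble(source = names(x$weights),
                 weight = unname(x$weights),
                 std_error = unname(x$std_errors))
}

#' Model-level summary of an admixture fit
#'
#' @param x a `paleo_qpadm`
#' @param ... unused
#' @return one-row tibble: `chisq`, `dof`, `p_value`, `n_snps`, `n_blocks`
#' @export
glance.paleo_qpadm <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, dof = x$dof, p_value = x$p_value,
                 n_snps = x$n_snps, n_blocks = x$n_blocks)
}

#' Tidy a sex-bias result
#'
#' @param x a `paleo_sexbias`
#' @param ... unused
#' @return the one-row decomposition tibble (pA, pX, z, F, M, P with CI)
#' @export
tidy.paleo_sexbias <- function(x, ...) x$decomposition

#' Compartment-level fit summary of a sex-bias result
#'
#' @param x a `paleo_sexbias`
#' @param ... unused
#' @return two-row tibble (`compartment` = autosomes/X) with fit stats
#' @export
glance.paleo_sexbias <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$autosomes), compartment = "autosomes"),
    dplyr::mutate(glance(x$X), compartment = "X")) |>
    dplyr::relocate("compartment")
}

#' Tidy a date estimate
#'
#' @param x a `paleo_date`
#' @param ... unused
#' @return plain tibble of the estimate row
#' @export
tidy.paleo_date <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "paleo_date")
  attr(out, "curve") <- NULL; attr(out, "fit") <- NULL
  out
}

#' Plot an ancestry-covariance decay curve
#'
#' @param object a `paleo_decay`
#' @param fit optional [fit_decay()] result to overlay
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.paleo_decay <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$distance, y = .data$covariance)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::labs(x = "genetic distance (Morgans)", y = "ancestry covariance") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(data = fit$fitted,
                                ggplot2::aes(y = .data$fitted),
                                color = "firebrick", linewidth = 0.8)
  }
  p
}

#' Plot reference PCA coordinates
#'
#' @param object a `paleo_pca`
#' @param projected optional [pca_project()] tibble overlaid as triangles
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.paleo_pca <- function(object, projected = NULL, ...) {
  p <- ggplot2::ggplot(object$reference_coords,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    color = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal()
  if (!is.null(projected)) {
    p <- p + ggplot2::geom_point(data = projected, shape = 17)
  }
  p
}

#' Plot pairwise-mismatch coefficients with degree bands
#'
#' @param classified output of [classify_degrees()]
#' @return a ggplot of normalized mismatch per pair with the class band
#'   boundaries
#' @export
plot_kinship <- function(classified) {
  pr <- classified$pairs[!classified$pairs$unknown, ]
  pr <- pr[order(pr$phi), ]
  pr$rank <- seq_len(nrow(pr))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$rank, y = .data$phi,
                                   color = .data$degree_class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.625, 0.8125, 0.90625, 0.953125),
                        linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "pair (sorted)", y = "normalized mismatch") +
    ggplot2::theme_minimal()
}
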