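#' @importFrom ggplot2 autoplot
NULL

#' Silhouette scan plot
#'
#' Mean silhouette width against candidate subgroup count, with the
#' selected K highlighted.
#'
#' @param object A `k_selection` from [select_k_silhouette()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_clusters, y = .data$silhouette)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = tab$n_clusters) +
    ggplot2::labs(x = "number of subgroups K", y = "mean silhouette width",
                  title = paste0("Silhouette scan (selected K = ",
                                 object$best_k, ")")) +
    ggplot2::theme_minimal()
}

#' Fused-embedding scatter of a pipeline fit
#'
#' Patients plotted in the first two fused-embedding dimensions, coloured
#' by subgroup.
#'
#' @param object A `subgroup_fit` from [fuse_pipeline()].
#' @param dims Which two embedding dimensions to show (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subgroup_fit <- function(object, dims = c(1, 2), ...) {
  basis <- object$fusion$fused$basis
  if (ncol(basis) < 2L) dims <- c(1L, 1L)
  df <- tibble::tibble(
    x = basis[, dims[1L]],
    y = basis[, dims[2L]],
    subgroup = factor(object$result$subgroups$subgroup)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$subgroup)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0("fused dim ", dims[1L]),
                  y = paste0("fused dim ", dims[2L]),
                  colour = "subgroup",
                  title = "Patients in the fused subspace") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves per subgroup
#'
#' Step curves of the Kaplan-Meier survival estimates underlying a log-rank
#' comparison, one per subgroup, annotated with the test p-value.
#'
#' @param object A `survival_comparison` from [logrank_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  fit <- object$fit
  strata_names <- sub("^grp=", "", rep(names(fit$strata), fit$strata))
  df <- tibble::tibble(
    time = fit$time,
    surv = fit$surv,
    subgroup = factor(strata_names)
  )
  # prepend the (0, 1) anchor of each curve
  anchors <- tibble::tibble(time = 0, surv = 1,
                            subgroup = factor(levels(df$subgroup),
                                              levels = levels(df$subgroup)))
  df <- dplyr::bind_rows(anchors, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$subgroup)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "subgroup",
                  title = sprintf("Kaplan-Meier curves (log-rank p = %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Scree plot of a PCA-reduced view
#'
#' Cumulative explained-variance ratio per component with the retention
#' threshold marked.
#'
#' @param object A `pca_view` from [pca_reduce()].
#' @param threshold Reference line (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_view <- function(object, threshold = 0.95, ...) {
  df <- tidy.pca_view(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$cumulative_ratio)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "component", y = "cumulative explained variance",
                  title = paste0("Scree (", object$n_components,
                                 " components retained)")) +
    ggplot2::theme_minimal()
}
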