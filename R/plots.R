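#' Stacked membership bar plot of an admixture fit
#'
#' The conventional admixture bar plot: one bar per sample, filled by its
#' posterior-mean membership in each cluster, ordered by population label
#' then by dominant cluster membership.
#'
#' @param object An `ssr_structure` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_structure <- function(object, ...) {
  long <- tidy(object)
  memb <- assign_membership(object)
  ord <- order(if (!is.null(long$pop)) long$pop[match(rownames(object$q) %||%
                 unique(long$sample), long$sample)] else rep(1, nrow(object$q)),
               memb$cluster, -memb$q_max)
  ids <- (rownames(object$q) %||% as.character(seq_len(nrow(object$q))))[ord]
  long$sample <- factor(long$sample, levels = ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$q,
                                     fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "membership q", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Evanno delta-K profile
#'
#' @param object An `ssr_evanno` table.
#' @param ... Unused.
#' @return A ggplot object with the delta-K curve and the selected K marked.
#' @export
autoplot.ssr_evanno <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$delta_K), ],
                  ggplot2::aes(x = .data$K, y = .data$delta_K)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best_k(object), linetype = 2) +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' BIC curve of the cluster search
#'
#' @param object An `ssr_clusters` result.
#' @param ... Unused.
#' @return A ggplot object; the BIC minimum is marked.
#' @export
autoplot.ssr_clusters <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$K, y = .data$BIC)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2) +
    ggplot2::theme_minimal()
}

#' Discriminant-space scatter of a DAPC fit
#'
#' Samples on the first two discriminant axes (or LD1 against group when a
#' single axis exists), coloured by group, centroids marked.
#'
#' @param object An `ssr_dapc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_dapc <- function(object, ...) {
  df <- tidy(object)
  if (object$n_da >= 2L) {
    cen <- tibble::as_tibble(object$centroids[, 1:2, drop = FALSE],
                             .name_repair = "minimal")
    names(cen) <- c("LD1", "LD2")
    cen$group <- rownames(object$centroids)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                     colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_point(data = cen, shape = 3, size = 4,
                          show.legend = FALSE) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, fill = .data$group)) +
      ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
      ggplot2::theme_minimal()
  }
}

#' Cross-validation success curve
#'
#' @param object An `ssr_xval` result.
#' @param ... Unused.
#' @return A ggplot object; the recommended PC count is marked.
#' @export
autoplot.ssr_xval <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$n_pcs, y = .data$mean_success)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$recommended, linetype = 2) +
    ggplot2::labs(y = "holdout assignment success") +
    ggplot2::theme_minimal()
}
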