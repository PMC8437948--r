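#' Tidy a similarity report
#' @param x a `similarity_report`.
#' @param ... unused.
#' @return tibble with columns `metric`, `value`, `direction` (whether
#'   larger or smaller values mean more similar).
#' @method tidy similarity_report
#' @export
tidy.similarity_report <- function(x, ...) {
  tibble::tibble(
    metric = c("dice", "gce", "voi", "hd", "ri"),
    value = c(x$dice, x$gce, x$voi, x$hd, x$ri),
    direction = c("higher", "lower", "lower", "lower", "higher"))
}

#' Tidy an evaluation report (per-fold metrics)
#' @param x an `eval_report` from [cross_validate()].
#' @param ... unused.
#' @return long tibble: `rep`, `fold`, `metric`, `value`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -c("rep", "fold"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return one-row tibble of the seven aggregate metric means plus
#'   `classifier`, `k_folds`, `repeats`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  out <- tibble::as_tibble(as.list(setNames(x$aggregate$mean,
                                            x$aggregate$metric)))
  dplyr::bind_cols(tibble::tibble(classifier = x$spec$kind,
                                  k_folds = x$cv$k_folds,
                                  repeats = x$cv$repeats), out)
}

#' Tidy a feature ranking
#' @param x a `ranked_features`.
#' @param ... unused.
#' @return tibble `rank`, `feature`, `score`, `method`.
#' @method tidy ranked_features
#' @export
tidy.ranked_features <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$order), feature = x$order,
                 score = unname(x$scores[x$order]), method = x$method)
}

#' Tidy a consensus selection
#' @param x a `consensus_result`.
#' @param ... unused.
#' @return tibble `feature`, one logical column per method, `selected`.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  feats <- sort(unique(unlist(x$per_method_top)))
  out <- tibble::tibble(feature = feats)
  for (m in names(x$per_method_top))
    out[[m]] <- feats %in% x$per_method_top[[m]]
  out$selected <- feats %in% x$selected
  out
}

#' Plot per-fold metric distributions of an evaluation report
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%s: %d-fold CV x %d repeats",
                                  object$spec$kind, object$cv$k_folds,
                                  object$cv$repeats)) +
    ggplot2::theme_minimal()
}

#' Plot a similarity report as a labelled bar chart
#' @param object a `similarity_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot similarity_report
#' @export
autoplot.similarity_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "value",
                  fill = "more similar when") +
    ggplot2::theme_minimal()
}

#' Display a lesion scene and its ground-truth masks
#' @param scene a `lesion_scene`.
#' @param ... unused.
#' @return a ggplot object (image raster with mask contours).
#' @export
plot_scene <- function(scene, ...) {
  img <- scene$image / 255
  h <- nrow(scene$lesion_mask); w <- ncol(scene$lesion_mask)
  df <- expand.grid(y = seq_len(h), x = seq_len(w))
  df$col <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  df$lesion <- as.vector(scene$lesion_mask)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("severity: %s (E=%d, S=%d)",
                                  scene$severity_group,
                                  scene$erythema_score, scene$scale_score)) +
    ggplot2::theme_void()
  if (any(scene$lesion_mask))
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$lesion)),
                                   breaks = 0.5, colour = "yellow",
                                   linewidth = 0.3)
  p
}

#' @export
print.lesion_scene <- function(x, ...) {
  cat(sprintf("<lesion_scene> %d x %d, E=%d S=%d (%s), lesion fraction %.3f\n",
              nrow(x$lesion_mask), ncol(x$lesion_mask), x$erythema_score,
              x$scale_score, x$severity_group, mean(x$lesion_mask)))
  invisible(x)
}
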