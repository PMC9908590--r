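#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_polygon
#'   scale_fill_gradientn scale_y_reverse coord_equal labs theme_minimal
#' @importFrom generics tidy glance
NULL

#' Tidy an agreement report
#'
#' One row per (level, metric), broom-style, so reports from many slides
#' stack with `bind_rows()` and summarise with dplyr.
#'
#' @param x An `agreement_report` from [compare_annotations()].
#' @param ... Unused.
#' @return Tibble (`wsi_id`, `level`, `metric`, `label`, `value`).
#' @export
tidy.agreement_report <- function(x, ...) {
  bind_rows(
    tibble(level = "wsi", metric = "agree", label = NA_character_,
           value = as.numeric(x$wsi$agree)),
    tibble(level = "patch_class", metric = c("kappa", "p_o", "p_e"),
           label = NA_character_,
           value = c(x$patch_class$kappa, x$patch_class$p_o, x$patch_class$p_e)),
    tibble(level = "patch_subtype", metric = c("kappa", "p_o", "p_e"),
           label = NA_character_,
           value = c(x$patch_subtype$kappa, x$patch_subtype$p_o, x$patch_subtype$p_e)),
    tibble(level = "pixel", metric = "dice", label = x$pixel_dice$label,
           value = x$pixel_dice$dice),
    tibble(level = "caption", metric = "bleu1", label = NA_character_,
           value = x$bleu1_mean)
  ) %>% mutate(wsi_id = x$wsi_id, .before = 1)
}

#' @rdname tidy.agreement_report
#' @return `glance` returns a one-row summary.
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(
    wsi_id = x$wsi_id,
    wsi_agree = x$wsi$agree,
    patch_kappa_class = x$patch_class$kappa,
    patch_kappa_subtype = x$patch_subtype$kappa,
    mean_dice = mean(x$pixel_dice$dice),
    bleu1_mean = x$bleu1_mean,
    n_caption_pairs = nrow(x$captions)
  )
}

#' Tidy a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return Long tibble (`label`, `metric`, `value`).
#' @export
tidy.classification_report <- function(x, ...) {
  x$per_class %>%
    tidyr::pivot_longer(c("recall", "precision"),
                        names_to = "metric", values_to = "value") %>%
    select("label", "metric", "value", "support")
}

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n, n_classes = nrow(x$per_class))
}

#' Plot an attention heatmap grid
#'
#' @param object A `heatmap_grid` from [attention_heatmap()].
#' @param ... Unused.
#' @return A ggplot object (tiles of dwell seconds, y increasing downward
#'   to match image coordinates).
#' @export
autoplot.heatmap_grid <- function(object, ...) {
  long <- tidyr::expand_grid(
    cell_j = seq_len(nrow(object$cells)) - 1L,
    cell_i = seq_len(ncol(object$cells)) - 1L
  ) %>% mutate(dwell_s = as.numeric(t(object$cells)))
  ggplot(long, aes(x = .data$cell_i, y = .data$cell_j, fill = .data$dwell_s)) +
    geom_tile() +
    scale_fill_gradientn(colours = c("#FFFFFF", "#FFEDA0", "#FEB24C", "#F03B20")) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "cell i", y = "cell j", fill = "dwell (s)",
         title = sprintf("Attention heatmap (%d px cells)", object$cell_px)) +
    theme_minimal()
}

#' Plot the regions of an annotation document
#'
#' @param object A [wsi_annotation()].
#' @param ... Unused.
#' @return A ggplot object: polygons colored by class, reason-layer regions
#'   drawn with dashed borders.
#' @export
autoplot.wsi_annotation <- function(object, ...) {
  rg <- object$regions
  df <- bind_rows(lapply(seq_len(nrow(rg)), function(k) {
    p <- rg$polygon[[k]]
    tibble(x = p[, 1], y = p[, 2], id = rg$id[k],
           layer = rg$layer[k], class_label = rg$class_label[k])
  }))
  ggplot(df, aes(x = .data$x, y = .data$y, group = .data$id,
                 fill = .data$class_label, linetype = .data$layer)) +
    geom_polygon(alpha = 0.4, colour = "grey20") +
    scale_y_reverse() +
    coord_equal(xlim = c(0, object$width), ylim = c(object$height, 0)) +
    labs(title = sprintf("%s (%s phase)", object$wsi_id, object$phase),
         fill = "class", linetype = "layer") +
    theme_minimal()
}

#' Plot a clustering of abnormal patches
#'
#' @param object Output of [dbscan_clusters()].
#' @param ... Unused.
#' @return A ggplot object; noise points are grey crosses.
#' @export
plot_clusters <- function(object, ...) {
  df <- object %>% mutate(
    cluster_lab = ifelse(is.na(.data$cluster), "noise", paste0("cluster ", .data$cluster))
  )
  ggplot(df, aes(x = .data$i, y = .data$j, colour = .data$cluster_lab,
                 shape = is.na(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 4), guide = "none") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "grid i", y = "grid j", colour = NULL,
         title = "Lesion clusters on the patch grid") +
    theme_minimal()
}
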