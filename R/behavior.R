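#' Viewport dwell intervals of a behavioral trace
#'
#' Each field-of-view or magnification event opens an interval that the next
#' such event (or the end of the trace) closes: last-event-holds semantics.
#' Voice/undo/delete events never close an interval. The viewport rectangle
#' is the screen size divided by the current magnification, centered on the
#' current field-of-view center and clipped to the slide bounds. Intervals
#' longer than `idle_cap_s` are truncated (unattended sessions would
#' otherwise dominate every dwell statistic).
#'
#' @param trace A [wsi_trace()].
#' @param slide_px Slide size `c(width, height)` in level-0 pixels.
#' @param base_magnification Magnification at which one screen pixel equals
#'   one level-0 pixel (default 1: a magnification event with `factor = 2`
#'   shows half the level-0 extent).
#' @param idle_cap_s Maximum dwell attributed to one interval, seconds.
#' @return Tibble (`t_start_ms`, `dwell_s`, `cx`, `cy`, `magnification`,
#'   `x0`, `y0`, `x1`, `y1`) with half-open rectangles `[x0,x1) x [y0,y1)`.
#' @export
viewport_intervals <- function(trace, slide_px, base_magnification = 1,
                               idle_cap_s = 120) {
  stopifnot(inherits(trace, "wsi_trace"))
  ev <- trace$events
  if (!any(ev$type == "fov_center_change")) {
    wsianno_abort("EMPTY_TRACE", "trace has no field-of-view events")
  }
  drivers <- ev %>% filter(.data$type %in% c("fov_center_change", "magnification"))
  end_ms <- max(ev$t_ms)
  cur_x <- NA_real_; cur_y <- NA_real_; cur_mag <- base_magnification
  out <- list()
  for (k in seq_len(nrow(drivers))) {
    e <- drivers[k, ]
    if (e$type == "fov_center_change") {
      cur_x <- e$x; cur_y <- e$y
    } else {
      cur_mag <- e$factor
    }
    if (is.na(cur_x)) next  # magnification before any fov center: no viewport yet
    t_next <- if (k < nrow(drivers)) drivers$t_ms[k + 1] else end_ms
    dwell <- min((t_next - e$t_ms) / 1000, idle_cap_s)
    if (dwell <= 0) next
    vw <- trace$screen_px[1] / cur_mag
    vh <- trace$screen_px[2] / cur_mag
    out[[length(out) + 1]] <- tibble(
      t_start_ms = e$t_ms, dwell_s = dwell,
      cx = cur_x, cy = cur_y, magnification = cur_mag,
      x0 = max(0, cur_x - vw / 2), y0 = max(0, cur_y - vh / 2),
      x1 = min(slide_px[1], cur_x + vw / 2), y1 = min(slide_px[2], cur_y + vh / 2)
    )
  }
  if (length(out) == 0) {
    wsianno_abort("EMPTY_TRACE", "no dwell intervals could be formed")
  }
  bind_rows(out)
}

#' Attention heatmap from a behavioral trace
#'
#' Accumulates dwell seconds onto a grid of `cell_px`-sized cells: each
#' interval deposits its full dwell into every cell its viewport rectangle
#' covers, so the grid total equals the sum over intervals of
#' `dwell_s x covered_cell_count` (cell-seconds are conserved).
#'
#' @inheritParams viewport_intervals
#' @param cell_px Cell side in level-0 pixels (256 aligns cells to patches).
#' @return A `heatmap_grid`: list with `cells` (rows = y, cols = x, dwell
#'   seconds), `cell_px`, `total_dwell_s` (sum over intervals), `slide_px`.
#' @export
attention_heatmap <- function(trace, slide_px, cell_px = 256,
                              base_magnification = 1, idle_cap_s = 120) {
  iv <- viewport_intervals(trace, slide_px, base_magnification, idle_cap_s)
  nx <- ceiling(slide_px[1] / cell_px); ny <- ceiling(slide_px[2] / cell_px)
  cells <- matrix(0, nrow = ny, ncol = nx)
  for (k in seq_len(nrow(iv))) {
    # half-open rect -> cells it intersects
    ci0 <- floor(iv$x0[k] / cell_px); ci1 <- ceiling(iv$x1[k] / cell_px) - 1
    cj0 <- floor(iv$y0[k] / cell_px); cj1 <- ceiling(iv$y1[k] / cell_px) - 1
    ci <- max(0, ci0):min(nx - 1, ci1)
    cj <- max(0, cj0):min(ny - 1, cj1)
    cells[cj + 1, ci + 1] <- cells[cj + 1, ci + 1] + iv$dwell_s[k]
  }
  structure(
    list(cells = cells, cell_px = cell_px,
         total_dwell_s = sum(iv$dwell_s), slide_px = slide_px),
    class = "heatmap_grid"
  )
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf(
    "<heatmap_grid %dx%d cells of %d px: %.1f dwell-s, %.1f cell-s>\n",
    ncol(x$cells), nrow(x$cells), x$cell_px, x$total_dwell_s, sum(x$cells)
  ))
  invisible(x)
}

#' Attribute dwell time to annotation regions
#'
#' Each interval's dwell is attributed to the region containing the
#' interval's viewport center (center-in-polygon); dwell whose center lies
#' in no region is unattributed, so the mapping total never exceeds the
#' trace total.
#'
#' @inheritParams viewport_intervals
#' @param regions Region table of a [wsi_annotation()].
#' @return Tibble (`region_id`, `dwell_s`), one row per region that
#'   received dwell.
#' @export
dwell_by_region <- function(trace, regions, slide_px,
                            base_magnification = 1, idle_cap_s = 120) {
  iv <- viewport_intervals(trace, slide_px, base_magnification, idle_cap_s)
  if (nrow(regions) == 0) {
    return(tibble(region_id = character(), dwell_s = numeric()))
  }
  acc <- setNames(numeric(nrow(regions)), regions$id)
  for (k in seq_len(nrow(iv))) {
    for (r in seq_len(nrow(regions))) {
      if (point_in_polygon(iv$cx[k], iv$cy[k], regions$polygon[[r]])) {
        acc[regions$id[r]] <- acc[regions$id[r]] + iv$dwell_s[k]
        break  # first containing region in table order takes the interval
      }
    }
  }
  tibble(region_id = names(acc), dwell_s = as.numeric(acc)) %>%
    filter(.data$dwell_s > 0)
}

#' Render a heatmap grid to a PNG file
#'
#' Deterministic rendering: a fixed color ramp over linearly normalized
#' dwell, one image pixel per cell (scaled up by `scale`).
#'
#' @param grid A `heatmap_grid` from [attention_heatmap()].
#' @param path Output PNG path.
#' @param scale Integer upscaling factor per cell.
#' @param colormap Vector of colors for the ramp (low to high).
#' @return `path`, invisibly.
#' @export
render_heatmap_png <- function(grid, path, scale = 8,
                               colormap = c("#FFFFFF", "#FFEDA0", "#FEB24C", "#F03B20")) {
  cells <- grid$cells
  mx <- max(cells)
  norm <- if (mx > 0) cells / mx else cells
  ramp <- grDevices::colorRamp(colormap)
  rgbvals <- ramp(as.numeric(norm)) / 255
  h <- nrow(cells); w <- ncol(cells)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgbvals[, ch], nrow = h, ncol = w)
  if (scale > 1) {
    img <- img[rep(seq_len(h), each = scale), rep(seq_len(w), each = scale), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Dump a heatmap grid as CSV
#'
#' @param grid A `heatmap_grid`.
#' @param path Output CSV path (long format: `cell_i`, `cell_j`, `dwell_s`).
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(grid, path) {
  long <- tidyr::expand_grid(
    cell_j = seq_len(nrow(grid$cells)) - 1L,
    cell_i = seq_len(ncol(grid$cells)) - 1L
  ) %>%
    mutate(dwell_s = as.numeric(t(grid$cells))) %>%
    select("cell_i", "cell_j", "dwell_s")
  readr::write_csv(long, path)
  invisible(path)
}
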