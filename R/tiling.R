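#' Patch grid specification
#'
#' Patches are half-open boxes on a regular grid: patch `(i, j)` covers
#' `[i*stride, i*stride + patch_size) x [j*stride, j*stride + patch_size)`
#' in level-0 pixels, with center `(i*stride + patch_size/2, j*stride +
#' patch_size/2)`. With `stride == patch_size` the grid tiles the plane:
#' every pixel belongs to exactly one patch.
#'
#' @param patch_size Patch side in pixels (default 256).
#' @param stride Grid stride in pixels (default `patch_size`).
#' @param magnification Nominal objective magnification of the source level.
#' @return A `patch_grid` list.
#' @export
patch_grid <- function(patch_size = 256, stride = patch_size, magnification = 20) {
  stopifnot(patch_size >= 1, stride >= 1)
  structure(
    list(patch_size = as.integer(patch_size), stride = as.integer(stride),
         magnification = magnification),
    class = "patch_grid"
  )
}

#' @rdname patch_grid
#' @param grid A `patch_grid`.
#' @param i,j Grid indices (0-based).
#' @return `patch_center` returns the center pixel `c(x, y)` of patch
#'   `(i, j)`.
#' @export
patch_center <- function(grid, i, j) {
  c(i * grid$stride + grid$patch_size / 2, j * grid$stride + grid$patch_size / 2)
}

# ---- Otsu ------------------------------------------------------------------

#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the split index `t` (0-based bin index) maximizing between-class
#' variance over the partition bins `<= t` vs `> t`; ties break to the
#' smallest maximizer so the result is deterministic.
#'
#' @param histogram Numeric vector of 256 non-negative counts.
#' @return Integer threshold in `0:254`.
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  histogram <- as.numeric(histogram) # integer counts overflow in the products
  total <- sum(histogram)
  if (total <= 0) {
    wsianno_abort("DEGENERATE_HISTOGRAM", "histogram has no mass")
  }
  if (sum(histogram > 0) < 2) {
    wsianno_abort("DEGENERATE_HISTOGRAM", "all histogram mass in a single bin")
  }
  levels <- 0:255
  w <- cumsum(histogram)
  m <- cumsum(histogram * levels)
  mg <- m[256]
  # between-class variance for split after bin t (t = 0..254)
  w0 <- w[1:255]
  mu0 <- m[1:255] / w0
  w1 <- total - w0
  mu1 <- (mg - m[1:255]) / w1
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  as.integer(which.max(sigma_b) - 1L)
}

#' Binary tissue mask of an RGB image
#'
#' Tissue absorbs light, so foreground pixels are those darker than the Otsu
#' threshold on a Gaussian-smoothed grayscale. A blank (single-bin) image
#' yields an all-background mask rather than an error.
#'
#' @param img RGB array (`h x w x 3`, values 0-255).
#' @param sigma Gaussian smoothing sigma in pixels.
#' @return Logical matrix of the image's height and width; `TRUE` = tissue.
#' @export
tissue_mask <- function(img, sigma = 2) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    wsianno_abort("FORMAT_ERROR", "tissue_mask needs an RGB (h x w x 3) array")
  }
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  smooth <- EBImage::gblur(gray, sigma = sigma)
  smooth <- pmin(pmax(smooth, 0), 255)
  h <- tabulate(floor(smooth) + 1L, nbins = 256)
  t <- tryCatch(
    otsu_threshold(h),
    wsianno_degenerate_histogram = function(e) NULL
  )
  if (is.null(t)) {
    return(matrix(FALSE, nrow = nrow(gray), ncol = ncol(gray)))
  }
  smooth <= t
}

# ---- point in polygon ------------------------------------------------------

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param px,py Point coordinates (vectors of equal length).
#' @param polygon Open polygon matrix (columns x, y).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  n <- nrow(polygon)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  out <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    on_edge <- FALSE
    for (e in seq_len(n)) {
      x1 <- xs[e]; y1 <- ys[e]; x2 <- xe[e]; y2 <- ye[e]
      # boundary check: point on segment
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (cross == 0 &&
          x >= min(x1, x2) && x <= max(x1, x2) &&
          y >= min(y1, y2) && y <= max(y1, y2)) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) inside <- !inside
      }
    }
    out[k] <- on_edge || inside
  }
  out
}

# ---- patch labeling --------------------------------------------------------

#' Label a patch center by the central-pixel rule
#'
#' A patch inherits the label of the decision-layer region containing its
#' center pixel (boundary counts as inside). When overlapping regions
#' disagree, the highest-priority (most severe) class wins.
#'
#' @param center `c(x, y)` of the patch center in level-0 pixels.
#' @param regions Decision-layer region table of a [wsi_annotation()].
#' @param priority Class ids ordered most to least severe.
#' @return One-row tibble (`label_class`, `label_subtype`), `NA`s when the
#'   center lies in no region.
#' @export
assign_patch_label <- function(center, regions,
                               priority = c("c_adenocarcinoma", "c_adenoma", "c_normal")) {
  regions <- regions[regions$layer == "decision", , drop = FALSE]
  hits <- which(map_lgl(regions$polygon, ~ point_in_polygon(center[1], center[2], .x)))
  if (length(hits) == 0) {
    return(tibble(label_class = NA_character_, label_subtype = NA_character_))
  }
  cand <- regions[hits, ]
  rank <- match(cand$class_label, priority)
  rank[is.na(rank)] <- length(priority) + 1L
  best <- cand[order(rank, cand$id), ][1, ]
  tibble(label_class = best$class_label, label_subtype = best$subtype_label)
}

#' Assign train/test splits at whole-slide granularity
#'
#' Splitting by slide guarantees that no slide (hence no patient section)
#' contributes patches to both sets.
#'
#' @param wsi_ids Unique slide ids.
#' @param test_fraction Fraction of slides assigned to test (ignored when
#'   `test_ids` is given).
#' @param test_ids Explicit slide ids for the test set.
#' @param seed Seed for the random assignment.
#' @return A tibble (`wsi_id`, `split`).
#' @export
split_by_wsi <- function(wsi_ids, test_fraction = 0.2, test_ids = NULL, seed = 1) {
  if (length(wsi_ids) == 0) {
    wsianno_abort("EMPTY_COHORT", "no slide ids supplied")
  }
  if (anyDuplicated(wsi_ids)) {
    wsianno_abort("FORMAT_ERROR", "slide ids must be unique")
  }
  if (is.null(test_ids)) {
    n_test <- max(1L, round(test_fraction * length(wsi_ids)))
    test_ids <- with_seed(substream_seed(seed, "split"),
                          sample(sort(wsi_ids), n_test))
  } else {
    miss <- setdiff(test_ids, wsi_ids)
    if (length(miss) > 0) {
      wsianno_abort("FORMAT_ERROR",
        paste0("test id(s) not in cohort: ", paste(miss, collapse = ", ")))
    }
  }
  tibble(wsi_id = wsi_ids, split = ifelse(wsi_ids %in% test_ids, "test", "train"))
}

#' Enumerate labeled candidate patches of one slide
#'
#' Walks the full grid over the slide, keeps patches whose boxes lie inside
#' the image and whose tissue fraction reaches `min_tissue`, and labels each
#' by the central-pixel rule.
#'
#' @param doc A [wsi_annotation()] carrying slide dimensions.
#' @param mask Tissue mask matrix from [tissue_mask()].
#' @param grid A [patch_grid()].
#' @param min_tissue Minimum tissue fraction for a valid patch.
#' @param priority Severity priority for overlapping regions.
#' @return Patch record tibble (`wsi_id, i, j, x0, y0, label_class,
#'   label_subtype, tissue_frac`).
#' @export
enumerate_patches <- function(doc, mask, grid = patch_grid(),
                              min_tissue = 0.5,
                              priority = c("c_adenocarcinoma", "c_adenoma", "c_normal")) {
  W <- doc$width; H <- doc$height
  stopifnot(nrow(mask) == H, ncol(mask) == W)
  ps <- grid$patch_size; st <- grid$stride
  is <- 0:max(0, floor((W - ps) / st))
  js <- 0:max(0, floor((H - ps) / st))
  # cumulative-sum integral image for fast tissue fractions
  ii <- rbind(0, cbind(0, apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()))
  box_sum <- function(x0, y0) {
    ii[y0 + ps + 1, x0 + ps + 1] - ii[y0 + 1, x0 + ps + 1] -
      ii[y0 + ps + 1, x0 + 1] + ii[y0 + 1, x0 + 1]
  }
  out <- list()
  for (j in js) {
    for (i in is) {
      x0 <- i * st; y0 <- j * st
      if (x0 + ps > W || y0 + ps > H) next
      tf <- box_sum(x0, y0) / (ps * ps)
      if (tf < min_tissue) next
      ctr <- patch_center(grid, i, j)
      lab <- assign_patch_label(ctr, doc$regions, priority)
      out[[length(out) + 1]] <- tibble(
        wsi_id = doc$wsi_id, i = i, j = j, x0 = x0, y0 = y0,
        label_class = lab$label_class, label_subtype = lab$label_subtype,
        tissue_frac = tf
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(wsi_id = character(), i = integer(), j = integer(),
                  x0 = integer(), y0 = integer(), label_class = character(),
                  label_subtype = character(), tissue_frac = numeric()))
  }
  bind_rows(out)
}

#' Sample a class-balanced training manifest
#'
#' Draws per-class targets uniformly without replacement across the labeled
#' candidate patches of training slides. Normal-class patches are drawn only
#' from slides whose annotation contains no tumor region, so lesion-adjacent
#' "normal-looking" tissue on tumor slides never enters the normal class.
#'
#' @param patches Labeled candidate patches (rows from [enumerate_patches()],
#'   with a `split` column).
#' @param class_targets Named integer vector, patches wanted per class id.
#' @param tumor_wsis Character vector of slide ids containing tumor regions.
#' @param seed Sampling seed.
#' @param normal_class Class id of the normal class.
#' @return Manifest tibble with `split = "train"` and the sampling `seed`.
#' @export
sample_training_patches <- function(patches, class_targets, tumor_wsis,
                                    seed = 1, normal_class = "c_normal") {
  patches <- patches %>% filter(.data$split == "train", !is.na(.data$label_class))
  picks <- list()
  for (cls in names(class_targets)) {
    pool <- patches %>% filter(.data$label_class == cls)
    if (cls == normal_class) {
      pool <- pool %>% filter(!(.data$wsi_id %in% tumor_wsis))
    }
    want <- class_targets[[cls]]
    if (nrow(pool) < want) {
      wsianno_abort("INSUFFICIENT_PATCHES", paste0(
        "class '", cls, "' has ", nrow(pool), " candidate patches, ", want, " requested"
      ))
    }
    idx <- with_seed(substream_seed(seed, paste0("sample_", cls)),
                     sample(seq_len(nrow(pool)), want))
    picks[[cls]] <- pool[sort(idx), ]
  }
  bind_rows(picks) %>%
    mutate(split = "train", seed = as.integer(seed)) %>%
    arrange(.data$wsi_id, .data$label_class, .data$j, .data$i)
}

#' Tile a test slide with non-overlapping patches
#'
#' With `stride == patch_size` every foreground grid cell is emitted exactly
#' once; patch boxes are pairwise disjoint and unlabeled cells keep their
#' central-pixel label for evaluation.
#'
#' @inheritParams enumerate_patches
#' @return Patch record tibble with `split = "test"`.
#' @export
tile_test_wsi <- function(doc, mask, grid = patch_grid(), min_tissue = 0.5,
                          priority = c("c_adenocarcinoma", "c_adenoma", "c_normal")) {
  if (grid$stride != grid$patch_size) {
    wsianno_abort("FORMAT_ERROR", "test tiling requires stride == patch_size (no overlap)")
  }
  enumerate_patches(doc, mask, grid, min_tissue, priority) %>%
    mutate(split = "test")
}

# ---- scanline rasterization ------------------------------------------------

#' Rasterize a polygon onto sample points
#'
#' Even-odd scanline fill evaluated at the sample coordinates `xs` x `ys`
#' (typically pixel centers), consistent with [point_in_polygon()] off the
#' boundary but vectorized per row for whole-image work.
#'
#' @param polygon Open polygon matrix (columns x, y).
#' @param xs,ys Sample coordinates (ascending).
#' @return Logical matrix, `length(ys)` rows x `length(xs)` columns.
#' @export
polygon_raster_mask <- function(polygon, xs, ys) {
  n <- nrow(polygon)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- x1[c(2:n, 1)]; y2 <- y1[c(2:n, 1)]
  out <- matrix(FALSE, nrow = length(ys), ncol = length(xs))
  yr <- range(c(y1, y2))
  for (r in seq_along(ys)) {
    y <- ys[r]
    if (y < yr[1] || y > yr[2]) next
    cross <- (y1 > y) != (y2 > y)
    if (!any(cross)) next
    xint <- sort(x1[cross] + (y - y1[cross]) * (x2[cross] - x1[cross]) / (y2[cross] - y1[cross]))
    for (k in seq(1, length(xint) - 1, by = 2)) {
      out[r, xs >= xint[k] & xs <= xint[k + 1]] <- TRUE
    }
  }
  out
}
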