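#' Configuration of the synthetic desk-scale cohort
#'
#' The generator emulates the *structure* of a decision-to-reason annotated
#' colorectal cohort at desk scale: per-slide class mixture, multi-region
#' polygon annotations with class/subtype labels, reason-layer feature
#' regions with terminology-tag captions, bundles sharing one caption,
#' perturbed second annotators, and viewport traces biased toward lesions.
#' Textures are procedural (smooth / striped / speckled value noise), not
#' histology-realistic: the cohort tests pipeline structure, not biology.
#'
#' @param n_wsis Number of slides.
#' @param image_size Slide side in pixels (square slides).
#' @param class_mix Named fractions of normal / adenoma / adenocarcinoma
#'   slides (sums to 1). The default follows the rough published cohort
#'   proportions (about a quarter normal, an eighth adenoma-only, the rest
#'   containing adenocarcinoma).
#' @param regions_per_wsi Range (min, max) of decision regions per tumor
#'   slide.
#' @param reason_features_per_region Range of reason-layer feature regions
#'   per decision region.
#' @param caption_terms_mean Mean caption length in terms (default 4.4, the
#'   published cohort mean); realized as `1 + Poisson(mean - 1)` so every
#'   caption has at least one term and the configured mean is exact in
#'   expectation.
#' @param bundle_fraction Fraction of reason regions grouped into bundles.
#' @param annotator_flip_rate Probability a perturbed annotator flips a
#'   region's label.
#' @param boundary_jitter_px Max per-vertex jitter of a perturbed annotator.
#' @param dwell_lesion_bias Expected fraction of trace dwell whose viewport
#'   center lies inside a lesion.
#' @param seed Master seed; all randomness flows from it via named
#'   substreams.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_wsis = 6,
                         image_size = 512,
                         class_mix = c(c_normal = 0.25, c_adenoma = 0.125,
                                       c_adenocarcinoma = 0.625),
                         regions_per_wsi = c(2, 4),
                         reason_features_per_region = c(1, 3),
                         caption_terms_mean = 4.4,
                         bundle_fraction = 0.5,
                         annotator_flip_rate = 0.1,
                         boundary_jitter_px = 8,
                         dwell_lesion_bias = 0.8,
                         seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-8) {
    wsianno_abort("CONFIG_ERROR", "class_mix fractions must sum to 1")
  }
  rates <- c(bundle_fraction, annotator_flip_rate, dwell_lesion_bias)
  if (any(rates < 0 | rates > 1)) {
    wsianno_abort("CONFIG_ERROR", "rates must lie in [0, 1]")
  }
  if (image_size < 8 * max(regions_per_wsi)) {
    wsianno_abort("CONFIG_ERROR", "image too small for the requested region count")
  }
  if (caption_terms_mean < 1) {
    wsianno_abort("CONFIG_ERROR", "caption_terms_mean must be at least 1")
  }
  structure(
    list(
      n_wsis = n_wsis, image_size = image_size, class_mix = class_mix,
      regions_per_wsi = regions_per_wsi,
      reason_features_per_region = reason_features_per_region,
      caption_terms_mean = caption_terms_mean,
      bundle_fraction = bundle_fraction,
      annotator_flip_rate = annotator_flip_rate,
      boundary_jitter_px = boundary_jitter_px,
      dwell_lesion_bias = dwell_lesion_bias,
      seed = seed
    ),
    class = "synth_config"
  )
}

# blobby closed polygon around (cx, cy): radius modulated by two harmonics
blob_polygon <- function(cx, cy, r0, n_vertices = 16, wobble = 0.3) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  k1 <- sample(2:4, 1); k2 <- sample(5:7, 1)
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  r <- r0 * (1 + wobble * (0.7 * sin(k1 * theta + ph1) + 0.3 * sin(k2 * theta + ph2)))
  cbind(x = round(cx + r * cos(theta)), y = round(cy + r * sin(theta)))
}

smooth_noise <- function(h, w, sigma = 6) {
  n <- matrix(runif(h * w), h, w)
  s <- EBImage::gblur(n, sigma = sigma)
  (s - min(s)) / (max(s) - min(s) + 1e-12)
}

# paint a class texture into img over mask; img modified and returned
paint_texture <- function(img, mask, class_id, noise) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  base <- switch(class_id,
    c_normal = c(235, 200, 220),          # smooth pale pink
    c_adenoma = c(200, 160, 200),         # striped mauve
    c_adenocarcinoma = c(170, 130, 185),  # speckled purple
    c(225, 205, 225)
  )
  tex <- switch(class_id,
    c_normal = 20 * (noise - 0.5),
    c_adenoma = 25 * sin(xs / 5) + 15 * (noise - 0.5),
    c_adenocarcinoma = -60 * (noise > 0.72) + 15 * (noise - 0.5),
    15 * (noise - 0.5)
  )
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[mask] <- pmin(pmax(base[ch] + tex[mask], 0), 255)
    img[, , ch] <- layer
  }
  img
}

children_of <- function(tree, parent) {
  tb <- as_tibble(tree)
  tb$id[!is.na(tb$parent_id) & tb$parent_id == parent]
}

sample_caption_terms <- function(pool, mean_terms) {
  n_terms <- 1 + rpois(1, mean_terms - 1)
  sample(pool, n_terms, replace = n_terms > length(pool))
}

# non-overlapping lesion centers on a coarse slot grid
lesion_slots <- function(image_size, n, margin) {
  per_side <- max(2, ceiling(sqrt(n)))
  step <- (image_size - 2 * margin) / per_side
  slots <- tidyr::expand_grid(a = seq_len(per_side), b = seq_len(per_side)) %>%
    mutate(
      cx = margin + (.data$a - 0.5) * step,
      cy = margin + (.data$b - 0.5) * step
    )
  slots[sample(nrow(slots), n), ]
}

generate_slide <- function(wsi_id, class_id, cfg, tree, seed) {
  with_seed(seed, {
    S <- cfg$image_size
    img <- array(255, dim = c(S, S, 3))
    xs <- seq_len(S) - 0.5
    ys <- seq_len(S) - 0.5

    # one large tissue blob on the white background
    tissue_poly <- blob_polygon(S / 2, S / 2, r0 = S * 0.38, n_vertices = 24, wobble = 0.15)
    tissue_mask_gt <- polygon_raster_mask(tissue_poly, xs, ys)
    noise <- smooth_noise(S, S)
    img <- paint_texture(img, tissue_mask_gt, "c_normal", noise)

    regions <- empty_region_table()
    bundles <- empty_bundle_table()
    reason_rows <- list()

    n_regions <- sample(cfg$regions_per_wsi[1]:cfg$regions_per_wsi[2], 1)
    if (class_id == "c_normal") {
      # normal slides: only normal areas labeled
      sub <- children_of(tree, "c_normal")[1]
      poly <- blob_polygon(S / 2, S / 2, r0 = S * 0.3, n_vertices = 12, wobble = 0.2)
      regions <- bind_rows(regions, anno_region(
        id = paste0(wsi_id, "_d1"), polygon = poly, layer = "decision",
        class_label = "c_normal", subtype_label = sub, created_ms = 1000
      ))
    } else {
      slots <- lesion_slots(S, n_regions, margin = S * 0.22)
      subtypes <- children_of(tree, class_id)
      for (k in seq_len(n_regions)) {
        sub <- sample(subtypes, 1)
        r0 <- S * runif(1, 0.07, 0.11)
        poly <- blob_polygon(slots$cx[k], slots$cy[k], r0 = r0, wobble = 0.25)
        poly[, 1] <- pmin(pmax(poly[, 1], 1), S - 1)
        poly[, 2] <- pmin(pmax(poly[, 2], 1), S - 1)
        did <- paste0(wsi_id, "_d", k)
        regions <- bind_rows(regions, anno_region(
          id = did, polygon = poly, layer = "decision",
          class_label = class_id, subtype_label = sub,
          created_ms = 1000 * k
        ))
        lesion_mask <- polygon_raster_mask(poly, xs, ys)
        img <- paint_texture(img, lesion_mask & tissue_mask_gt, class_id, noise)

        # reason-layer features inside the lesion
        reason_pool <- children_of(tree, sub)
        n_feat <- sample(cfg$reason_features_per_region[1]:cfg$reason_features_per_region[2], 1)
        for (f in seq_len(n_feat)) {
          fp <- blob_polygon(slots$cx[k] + runif(1, -r0 / 3, r0 / 3),
                             slots$cy[k] + runif(1, -r0 / 3, r0 / 3),
                             r0 = r0 * runif(1, 0.3, 0.5), n_vertices = 10)
          fp[, 1] <- pmin(pmax(fp[, 1], 1), S - 1)
          fp[, 2] <- pmin(pmax(fp[, 2], 1), S - 1)
          rid <- paste0(did, "_r", f)
          terms <- sample_caption_terms(reason_pool, cfg$caption_terms_mean)
          regions <- bind_rows(regions, anno_region(
            id = rid, polygon = fp, layer = "reason",
            class_label = class_id, subtype_label = sub,
            reason_labels = terms, created_ms = 1000 * k + 100 * f
          ))
          reason_rows[[length(reason_rows) + 1]] <- tibble(
            id = rid, subtype = sub, decision = did
          )
        }
      }
      # bundles: group reason regions sharing a subtype
      rr <- bind_rows(reason_rows)
      if (nrow(rr) >= 2 && cfg$bundle_fraction > 0) {
        n_bundled <- round(cfg$bundle_fraction * nrow(rr))
        by_sub <- split(rr$id, rr$subtype)
        b_idx <- 0
        for (sub in names(by_sub)) {
          ids <- by_sub[[sub]]
          while (length(ids) >= 2 && n_bundled >= 2) {
            take <- min(length(ids), sample(2:3, 1), n_bundled)
            if (take < 2) break
            b_idx <- b_idx + 1
            terms <- sample_caption_terms(children_of(tree, sub), cfg$caption_terms_mean)
            bundles <- bind_rows(bundles, anno_bundle(
              id = paste0(wsi_id, "_b", b_idx),
              member_region_ids = ids[seq_len(take)],
              caption_terms = terms,
              caption_diagnosis = as_tibble(tree)$name[as_tibble(tree)$id == sub]
            ))
            ids <- ids[-seq_len(take)]
            n_bundled <- n_bundled - take
          }
        }
      }
    }

    doc <- wsi_annotation(
      wsi_id = wsi_id, annotator_id = "synth_a1", phase = "fine",
      width = S, height = S, regions = regions, bundles = bundles,
      slide_caption = paste0("synthetic slide, dominant class ", class_id),
      audit_status = "submitted"
    )
    list(doc = doc, image = img, tissue_frac = mean(tissue_mask_gt))
  })
}

#' Generate a synthetic annotated cohort
#'
#' Produces, for each slide, a rendered RGB image (white background, smooth
#' pale-pink tissue, class-specific lesion textures: smooth for normal,
#' striped for adenoma, speckled for adenocarcinoma), a valid fine-phase
#' annotation document, and ground truth sufficient to score every
#' downstream operation. Deterministic under `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A `synth_cohort` list: `docs` (named list of [wsi_annotation()]),
#'   `images` (named list of RGB arrays), `ground_truth` (tibble with
#'   `wsi_id`, `class`, `tissue_frac`, `n_regions`, `n_bundles`), `tree`
#'   (the bundled terminology), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tree <- crc_terminology()
  classes <- with_seed(substream_seed(config$seed, "classes"), {
    n_per <- round(config$class_mix * config$n_wsis)
    while (sum(n_per) < config$n_wsis) n_per[which.max(config$class_mix)] <- n_per[which.max(config$class_mix)] + 1
    while (sum(n_per) > config$n_wsis) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1
    sample(rep(names(config$class_mix), times = n_per))
  })
  docs <- list(); images <- list(); gt <- list()
  for (k in seq_len(config$n_wsis)) {
    wsi_id <- sprintf("synth%03d", k)
    sl <- generate_slide(wsi_id, classes[k], config, tree,
                         seed = substream_seed(config$seed, paste0("slide_", k)))
    docs[[wsi_id]] <- sl$doc
    images[[wsi_id]] <- sl$image
    gt[[k]] <- tibble(
      wsi_id = wsi_id, class = classes[k], tissue_frac = sl$tissue_frac,
      n_regions = nrow(sl$doc$regions), n_bundles = nrow(sl$doc$bundles)
    )
  }
  structure(
    list(docs = docs, images = images, ground_truth = bind_rows(gt),
         tree = tree, config = config),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort: %d slides of %d px, seed %d>\n",
              x$config$n_wsis, x$config$image_size, x$config$seed))
  print(x$ground_truth)
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same formats all loaders consume: per-slide PNG image,
#' annotation JSON, region GeoJSON, plus the terminology TSV and a ground
#' truth CSV. Repeated writes of the same cohort are byte-identical.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_terminology(cohort$tree, file.path(dir, "terminology.tsv"))
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  for (wsi_id in names(cohort$docs)) {
    write_rgb(cohort$images[[wsi_id]], file.path(dir, paste0(wsi_id, ".png")))
    save_annotation(cohort$docs[[wsi_id]], file.path(dir, paste0(wsi_id, ".json")))
    save_regions_geojson(cohort$docs[[wsi_id]], file.path(dir, paste0(wsi_id, ".geojson")))
  }
  invisible(dir)
}

#' Simulate a second annotator by perturbing a document
#'
#' Each region's label is flipped with probability `flip_rate` to a
#' uniformly chosen *different* same-level label (class flips re-draw the
#' subtype under the new class and reason labels under the new subtype, so
#' the perturbed document stays valid), and every polygon vertex is
#' jittered by independent uniform integer offsets in `[-jitter_px,
#' jitter_px]`. The returned edit log records every change and is the
#' ground truth for [audit_diff()] and agreement recovery tests.
#'
#' @param doc A valid [wsi_annotation()].
#' @param tree The [terminology_tree()] the document uses.
#' @param flip_rate Per-region label flip probability.
#' @param jitter_px Max absolute vertex jitter in pixels.
#' @param seed Seed.
#' @return List `doc` (perturbed copy, annotator id suffixed "_b") and
#'   `edit_log` tibble (`region_id`, `field`, `old`, `new`).
#' @export
perturb_annotator <- function(doc, tree, flip_rate = 0.1, jitter_px = 0, seed = 1) {
  stopifnot(inherits(doc, "wsi_annotation"))
  classes <- as_tibble(tree)$id[as_tibble(tree)$level == "class"]
  with_seed(substream_seed(seed, "perturb"), {
    rg <- doc$regions
    log <- list()
    for (k in seq_len(nrow(rg))) {
      if (flip_rate > 0 && runif(1) < flip_rate) {
        old_class <- rg$class_label[k]
        new_class <- sample(setdiff(classes, old_class), 1)
        rg$class_label[k] <- new_class
        log[[length(log) + 1]] <- tibble(
          region_id = rg$id[k], field = "class_label",
          old = old_class, new = new_class
        )
        if (!is.na(rg$subtype_label[k])) {
          new_sub <- sample(children_of(tree, new_class), 1)
          log[[length(log) + 1]] <- tibble(
            region_id = rg$id[k], field = "subtype_label",
            old = rg$subtype_label[k], new = new_sub
          )
          rg$subtype_label[k] <- new_sub
          if (length(rg$reason_labels[[k]]) > 0) {
            rg$reason_labels[[k]] <- sample(
              children_of(tree, new_sub), length(rg$reason_labels[[k]]),
              replace = TRUE
            )
          }
        }
      }
      if (jitter_px > 0) {
        p <- rg$polygon[[k]]
        jit <- matrix(sample(-jitter_px:jitter_px, length(p), replace = TRUE), nrow = nrow(p))
        p2 <- p + jit
        p2[, 1] <- pmin(pmax(p2[, 1], 0), doc$width - 1)
        p2[, 2] <- pmin(pmax(p2[, 2], 0), doc$height - 1)
        rg$polygon[[k]] <- p2
        log[[length(log) + 1]] <- tibble(
          region_id = rg$id[k], field = "polygon",
          old = NA_character_, new = sprintf("jitter<=%dpx", jitter_px)
        )
      }
    }
    doc_b <- doc
    doc_b$regions <- rg
    doc_b$annotator_id <- paste0(doc$annotator_id, "_b")
    list(
      doc = doc_b,
      edit_log = if (length(log) > 0) bind_rows(log) else
        tibble(region_id = character(), field = character(),
               old = character(), new = character())
    )
  })
}

#' Generate a behavioral trace over a document
#'
#' Field-of-view centers follow a jumpy random walk in which each new
#' center lies inside a lesion polygon with probability
#' `dwell_lesion_bias` (rejection-sampled), and uniformly over the rest of
#' the slide otherwise, echoing the observation that annotators dwell
#' longer on difficult lesion areas. Inter-event gaps are uniform in
#' [0.3 s, 2 s]; timestamps are strictly increasing; occasional
#' magnification events are interleaved.
#'
#' @param doc A [wsi_annotation()] with decision regions.
#' @param dwell_lesion_bias Probability a viewport center falls inside a
#'   lesion.
#' @param duration_s Approximate trace duration in seconds.
#' @param seed Seed.
#' @param screen_px Viewport size in screen pixels.
#' @return A [wsi_trace()].
#' @export
generate_trace <- function(doc, dwell_lesion_bias = 0.8, duration_s = 60,
                           seed = 1, screen_px = c(1920, 1080)) {
  lesions <- doc$regions %>%
    filter(.data$layer == "decision", .data$class_label != "c_normal")
  with_seed(substream_seed(seed, "trace"), {
    t <- 0
    rows <- list()
    while (t < duration_s * 1000) {
      in_lesion <- nrow(lesions) > 0 && runif(1) < dwell_lesion_bias
      if (in_lesion) {
        poly <- lesions$polygon[[sample(nrow(lesions), 1)]]
        repeat {
          x <- runif(1, min(poly[, 1]), max(poly[, 1]))
          y <- runif(1, min(poly[, 2]), max(poly[, 2]))
          if (point_in_polygon(x, y, poly)) break
        }
      } else {
        repeat {
          x <- runif(1, 0, doc$width)
          y <- runif(1, 0, doc$height)
          inside_any <- nrow(lesions) > 0 &&
            any(map_lgl(lesions$polygon, ~ point_in_polygon(x, y, .x)))
          if (!inside_any) break
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        t_ms = t, type = "fov_center_change", x = round(x), y = round(y),
        factor = NA_real_, pencil = NA_character_
      )
      t <- t + round(runif(1, 300, 2000))
      if (runif(1) < 0.1) {
        rows[[length(rows) + 1]] <- tibble(
          t_ms = t, type = "magnification", x = NA_real_, y = NA_real_,
          factor = sample(c(2, 4, 8), 1), pencil = NA_character_
        )
        t <- t + round(runif(1, 300, 2000))
      }
    }
    wsi_trace(doc$wsi_id, "synth_a1", bind_rows(rows), screen_px = screen_px)
  })
}
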