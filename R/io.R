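SCHEMA_VERSION <- "1.0"
TRACE_SCHEMA <- "wsianno-trace/1"

EVENT_TYPES <- c(
  "fov_center_change", "magnification", "pencil_switch",
  "voice_start", "voice_stop", "undo", "delete",
  "label_create", "label_modify"
)

# ---- annotation documents (versioned JSON) --------------------------------

check_integer_coords <- function(m, where) {
  if (any(m != floor(m))) {
    wsianno_abort("GEOMETRY_ERROR", paste0(
      "non-integer polygon coordinates in ", where,
      " (annotation pixels are discrete level-0 integers)"
    ))
  }
}

doc_to_list <- function(doc) {
  rg <- doc$regions
  regions <- lapply(seq_len(nrow(rg)), function(k) {
    p <- rg$polygon[[k]]
    check_integer_coords(p, paste0("region '", rg$id[k], "'"))
    list(
      id = rg$id[k], layer = rg$layer[k], pencil_shape = rg$pencil_shape[k],
      class_label = rg$class_label[k],
      subtype_label = rg$subtype_label[k],
      reason_labels = as.list(rg$reason_labels[[k]]),
      free_text = rg$free_text[k], voice_ref = rg$voice_ref[k],
      created_ms = rg$created_ms[k],
      polygon = lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))
    )
  })
  bd <- doc$bundles
  bundles <- lapply(seq_len(nrow(bd)), function(k) {
    list(
      id = bd$id[k],
      member_region_ids = as.list(bd$member_region_ids[[k]]),
      caption = list(
        terms = as.list(bd$caption_terms[[k]]),
        diagnosis_phrase = bd$caption_diagnosis[k]
      )
    )
  })
  list(
    schema_version = SCHEMA_VERSION,
    wsi_id = doc$wsi_id, annotator_id = doc$annotator_id,
    phase = doc$phase, width = doc$width, height = doc$height,
    slide_caption = doc$slide_caption, audit_status = doc$audit_status,
    events_ref = doc$events_ref,
    regions = regions, bundles = bundles
  )
}

need_key <- function(x, key, where) {
  if (!key %in% names(x)) {
    wsianno_abort("PARSE_ERROR", paste0("missing key '", key, "' in ", where))
  }
  x[[key]]
}

scalar_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)[1]

list_to_doc <- function(lst, where = "document") {
  ver <- need_key(lst, "schema_version", where)
  if (!identical(ver, SCHEMA_VERSION)) {
    wsianno_abort("VERSION_ERROR", paste0("unrecognized schema_version '", ver, "'"))
  }
  regions_raw <- need_key(lst, "regions", where)
  bundles_raw <- need_key(lst, "bundles", where)
  regions <- empty_region_table()
  for (r in regions_raw) {
    poly_raw <- need_key(r, "polygon", paste0("region '", r$id %||% "?", "'"))
    p <- do.call(rbind, lapply(poly_raw, as.numeric))
    check_integer_coords(p, paste0("region '", r$id %||% "?", "'"))
    regions <- bind_rows(regions, anno_region(
      id = need_key(r, "id", where), polygon = p,
      layer = need_key(r, "layer", where),
      class_label = need_key(r, "class_label", where),
      subtype_label = scalar_chr(r$subtype_label),
      reason_labels = unlist(r$reason_labels) %||% character(),
      pencil_shape = r$pencil_shape %||% "curve",
      free_text = scalar_chr(r$free_text),
      voice_ref = scalar_chr(r$voice_ref),
      created_ms = r$created_ms %||% 0
    ))
  }
  bundles <- empty_bundle_table()
  for (b in bundles_raw) {
    cap <- need_key(b, "caption", paste0("bundle '", b$id %||% "?", "'"))
    bundles <- bind_rows(bundles, anno_bundle(
      id = need_key(b, "id", where),
      member_region_ids = unlist(b$member_region_ids) %||% character(),
      caption_terms = unlist(cap$terms) %||% character(),
      caption_diagnosis = scalar_chr(cap$diagnosis_phrase)
    ))
  }
  wsi_annotation(
    wsi_id = need_key(lst, "wsi_id", where),
    annotator_id = need_key(lst, "annotator_id", where),
    phase = need_key(lst, "phase", where),
    width = need_key(lst, "width", where),
    height = need_key(lst, "height", where),
    regions = regions, bundles = bundles,
    slide_caption = scalar_chr(lst$slide_caption),
    audit_status = lst$audit_status %||% "draft",
    events_ref = scalar_chr(lst$events_ref)
  )
}

#' Save / load annotation documents as versioned JSON
#'
#' The on-disk format is pretty-printed JSON with a `schema_version` field,
#' stable key order and integer coordinates, so repeated saves of the same
#' document are byte-identical and diffs stay readable for audit.
#'
#' @param doc A [wsi_annotation()].
#' @param path File path.
#' @return `save_annotation` returns `path` invisibly; `load_annotation`
#'   returns a [wsi_annotation()].
#' @export
save_annotation <- function(doc, path) {
  stopifnot(inherits(doc, "wsi_annotation"))
  json <- jsonlite::toJSON(doc_to_list(doc), auto_unbox = TRUE, null = "null",
                           na = "null", pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_annotation
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) {
    wsianno_abort("PARSE_ERROR", paste0("no such file: ", path))
  }
  lst <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      wsianno_abort("PARSE_ERROR", paste0("unparseable JSON in ", path, ": ", conditionMessage(e)))
    }
  )
  list_to_doc(lst, where = path)
}

# ---- terminology (TSV) ----------------------------------------------------

#' Save / load a terminology table as TSV
#'
#' Columns `id`, `level`, `parent_id`, `name`, `order`; UTF-8; row order in
#' the file does not affect the resulting tree.
#'
#' @param tree A [terminology_tree()].
#' @param path File path.
#' @return `load_terminology` returns a [terminology_tree()].
#' @export
save_terminology <- function(tree, path) {
  stopifnot(inherits(tree, "terminology_tree"))
  readr::write_tsv(as_tibble(tree), path, na = "")
  invisible(path)
}

#' @rdname save_terminology
#' @export
load_terminology <- function(path) {
  if (!file.exists(path)) {
    wsianno_abort("PARSE_ERROR", paste0("no such file: ", path))
  }
  tb <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      id = readr::col_character(), level = readr::col_character(),
      parent_id = readr::col_character(), name = readr::col_character(),
      order = readr::col_integer()
    ), na = "", progress = FALSE),
    error = function(e) {
      wsianno_abort("PARSE_ERROR", paste0("unparseable TSV in ", path, ": ", conditionMessage(e)))
    }
  )
  if (nrow(tb) == 0) {
    wsianno_abort("EMPTY_TERMINOLOGY", paste0("terminology file is empty: ", path))
  }
  terminology_tree(tb)
}

# ---- behavioral traces (JSON Lines) ---------------------------------------

#' Construct an in-memory behavioral trace
#'
#' @param wsi_id,annotator_id Identifiers.
#' @param events A tibble with columns `t_ms`, `type`, and the per-type
#'   payload columns `x`, `y` (field-of-view center, level-0 px),
#'   `factor` (magnification), `pencil` (label id).
#' @param screen_px Viewport size in screen pixels, `c(width, height)`.
#' @return A `wsi_trace` object.
#' @export
wsi_trace <- function(wsi_id, annotator_id, events, screen_px = c(1920, 1080)) {
  events <- as_tibble(events)
  for (col in c("x", "y", "factor")) {
    if (!col %in% names(events)) events[[col]] <- NA_real_
  }
  if (!"pencil" %in% names(events)) events$pencil <- NA_character_
  bad <- setdiff(unique(events$type), EVENT_TYPES)
  if (length(bad) > 0) {
    wsianno_abort("TYPE_ERROR", paste0("unknown event type(s): ", paste(bad, collapse = ", ")))
  }
  if (is.unsorted(events$t_ms)) {
    wsianno_abort("TIME_ORDER_ERROR", "event timestamps must be non-decreasing")
  }
  structure(
    list(
      wsi_id = as.character(wsi_id), annotator_id = as.character(annotator_id),
      screen_px = as.numeric(screen_px),
      events = events %>% select("t_ms", "type", "x", "y", "factor", "pencil")
    ),
    class = "wsi_trace"
  )
}

#' @export
print.wsi_trace <- function(x, ...) {
  cat(sprintf(
    "<wsi_trace %s by %s: %d events over %.1f s>\n",
    x$wsi_id, x$annotator_id, nrow(x$events),
    (max(x$events$t_ms) - min(x$events$t_ms)) / 1000
  ))
  invisible(x)
}

event_payload_fields <- function(type) {
  switch(type,
    fov_center_change = c("x", "y"),
    magnification = "factor",
    pencil_switch = "pencil",
    character()
  )
}

#' Save / load behavioral traces as JSON Lines
#'
#' Line 1 is a header record carrying trace metadata; each following line is
#' one timestamped event. Timestamps must be non-decreasing in the file: the
#' loader verifies order (with the offending line number) rather than
#' silently re-sorting.
#'
#' @param trace A [wsi_trace()].
#' @param path File path.
#' @return `load_trace` returns a [wsi_trace()].
#' @export
save_trace <- function(trace, path) {
  stopifnot(inherits(trace, "wsi_trace"))
  header <- jsonlite::toJSON(list(
    schema = TRACE_SCHEMA, wsi_id = trace$wsi_id,
    annotator_id = trace$annotator_id,
    screen_w = trace$screen_px[1], screen_h = trace$screen_px[2]
  ), auto_unbox = TRUE, digits = NA)
  ev <- trace$events
  lines <- map_chr(seq_len(nrow(ev)), function(k) {
    rec <- list(t_ms = ev$t_ms[k], type = ev$type[k])
    for (f in event_payload_fields(ev$type[k])) rec[[f]] <- ev[[f]][k]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  })
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_trace
#' @export
load_trace <- function(path) {
  if (!file.exists(path)) {
    wsianno_abort("PARSE_ERROR", paste0("no such file: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) {
    wsianno_abort("PARSE_ERROR", paste0("empty trace file: ", path))
  }
  header <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  if (!identical(header$schema, TRACE_SCHEMA)) {
    wsianno_abort("VERSION_ERROR", paste0("unrecognized trace schema in ", path))
  }
  recs <- vector("list", length(lines) - 1L)
  last_t <- -Inf
  for (k in seq_along(recs)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[k + 1L], simplifyVector = FALSE),
      error = function(e) {
        wsianno_abort("PARSE_ERROR", paste0("bad JSON at line ", k + 1L, " of ", path))
      }
    )
    if (is.null(rec$type) || !(rec$type %in% EVENT_TYPES)) {
      wsianno_abort("TYPE_ERROR", paste0(
        "unknown event type '", rec$type %||% "?", "' at line ", k + 1L, " of ", path
      ))
    }
    if (is.null(rec$t_ms)) {
      wsianno_abort("PARSE_ERROR", paste0("missing t_ms at line ", k + 1L, " of ", path))
    }
    if (rec$t_ms < last_t) {
      wsianno_abort("TIME_ORDER_ERROR", paste0(
        "decreasing timestamp at line ", k + 1L, " of ", path
      ))
    }
    for (f in event_payload_fields(rec$type)) {
      if (is.null(rec[[f]])) {
        wsianno_abort("PARSE_ERROR", paste0(
          "event '", rec$type, "' at line ", k + 1L, " misses payload field '", f, "'"
        ))
      }
    }
    last_t <- rec$t_ms
    recs[[k]] <- tibble(
      t_ms = as.numeric(rec$t_ms), type = rec$type,
      x = as.numeric(rec$x %||% NA), y = as.numeric(rec$y %||% NA),
      factor = as.numeric(rec$factor %||% NA),
      pencil = scalar_chr(rec$pencil)
    )
  }
  events <- if (length(recs) > 0) bind_rows(recs) else
    tibble(t_ms = numeric(), type = character(), x = numeric(),
           y = numeric(), factor = numeric(), pencil = character())
  wsi_trace(header$wsi_id, header$annotator_id, events,
            screen_px = c(header$screen_w, header$screen_h))
}

# ---- region geometry (GeoJSON) --------------------------------------------

#' Export / import region polygons as GeoJSON
#'
#' One RFC 7946 Polygon feature per region with a closed outer ring (first
#' vertex repeated). Properties carry the layer, labels, and the containing
#' bundle id, so the geometry file is self-describing.
#'
#' @param doc A [wsi_annotation()].
#' @return `export_regions_geojson` returns the FeatureCollection as a list;
#'   use [jsonlite::toJSON()] (or [save_regions_geojson()]) to write it.
#' @export
export_regions_geojson <- function(doc) {
  stopifnot(inherits(doc, "wsi_annotation"))
  bundle_of <- character()
  for (k in seq_len(nrow(doc$bundles))) {
    for (m in doc$bundles$member_region_ids[[k]]) {
      bundle_of[m] <- doc$bundles$id[k]
    }
  }
  rg <- doc$regions
  feats <- lapply(seq_len(nrow(rg)), function(k) {
    p <- rg$polygon[[k]]
    check_integer_coords(p, paste0("region '", rg$id[k], "'"))
    ring <- rbind(p, p[1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) as.integer(ring[i, ])))
      ),
      properties = list(
        region_id = rg$id[k], wsi_id = doc$wsi_id, layer = rg$layer[k],
        pencil_shape = rg$pencil_shape[k],
        class_label = rg$class_label[k], subtype_label = rg$subtype_label[k],
        reason_labels = as.list(rg$reason_labels[[k]]),
        bundle_id = if (rg$id[k] %in% names(bundle_of)) bundle_of[[rg$id[k]]] else NA_character_
      )
    )
  })
  list(type = "FeatureCollection", features = feats)
}

#' @rdname export_regions_geojson
#' @param fc A FeatureCollection list as produced by `export_regions_geojson`.
#' @param wsi_id Slide id the imported regions belong to.
#' @export
import_regions_geojson <- function(fc, wsi_id) {
  if (!identical(fc$type, "FeatureCollection")) {
    wsianno_abort("GEOMETRY_ERROR", "not a FeatureCollection")
  }
  regions <- empty_region_table()
  for (ft in fc$features) {
    g <- ft$geometry
    if (!identical(g$type, "Polygon")) {
      wsianno_abort("GEOMETRY_ERROR",
        paste0("unsupported geometry type '", g$type %||% "?", "' (Polygon required)"))
    }
    ring <- do.call(rbind, lapply(g$coordinates[[1]], as.numeric))
    check_integer_coords(ring, paste0("feature '", ft$properties$region_id %||% "?", "'"))
    if (!all(ring[1, ] == ring[nrow(ring), ])) {
      wsianno_abort("GEOMETRY_ERROR", "outer ring is not closed")
    }
    pr <- ft$properties
    regions <- bind_rows(regions, anno_region(
      id = pr$region_id, polygon = ring[-nrow(ring), , drop = FALSE],
      layer = pr$layer, class_label = pr$class_label,
      subtype_label = scalar_chr(pr$subtype_label),
      reason_labels = unlist(pr$reason_labels) %||% character(),
      pencil_shape = pr$pencil_shape %||% "curve"
    ))
  }
  regions
}

#' @rdname export_regions_geojson
#' @param path File path for the GeoJSON document.
#' @export
save_regions_geojson <- function(doc, path) {
  fc <- export_regions_geojson(doc)
  writeLines(
    jsonlite::toJSON(fc, auto_unbox = TRUE, null = "null", na = "null",
                     pretty = TRUE, digits = NA),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' @rdname export_regions_geojson
#' @export
load_regions_geojson <- function(path, wsi_id) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  import_regions_geojson(fc, wsi_id)
}

# ---- patch manifests (CSV) ------------------------------------------------

MANIFEST_COLS <- c("wsi_id", "i", "j", "x0", "y0", "label_class",
                   "label_subtype", "tissue_frac", "split", "seed")

#' Write / read a patch manifest as CSV
#'
#' Fixed column order (`wsi_id, i, j, x0, y0, label_class, label_subtype,
#' tissue_frac, split, seed`) and deterministic formatting, so identical
#' inputs give byte-identical files.
#'
#' @param records Patch record tibble (see [tile_test_wsi()] and
#'   [sample_training_patches()]).
#' @param path File path.
#' @return `read_patch_manifest` returns the manifest tibble.
#' @export
write_patch_manifest <- function(records, path) {
  records <- as_tibble(records)
  for (col in setdiff(MANIFEST_COLS, names(records))) {
    records[[col]] <- if (col %in% c("label_class", "label_subtype", "split", "wsi_id")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  out <- records %>%
    select(all_of(MANIFEST_COLS)) %>%
    mutate(tissue_frac = round(.data$tissue_frac, 6))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    wsi_id = readr::col_character(), i = readr::col_integer(),
    j = readr::col_integer(), x0 = readr::col_integer(),
    y0 = readr::col_integer(), label_class = readr::col_character(),
    label_subtype = readr::col_character(),
    tissue_frac = readr::col_double(), split = readr::col_character(),
    seed = readr::col_integer()
  ), na = "", progress = FALSE)
}

# ---- plain raster images ---------------------------------------------------

#' Read / write plain RGB raster images
#'
#' Images are carried in memory as `height x width x 3` numeric arrays with
#' values 0-255. Plain PNG/TIFF rasters are first-class inputs so the whole
#' pipeline is testable without pyramidal slides.
#'
#' @param path File path (.png or .tif/.tiff).
#' @return `read_rgb` returns the image array.
#' @export
read_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    # tiff via EBImage to avoid an extra direct dependency
    a <- EBImage::imageData(EBImage::readImage(path))
    aperm(a, c(2, 1, 3))
  } else {
    wsianno_abort("FORMAT_ERROR", paste0("unsupported image extension: .", ext))
  }
  if (length(dim(arr)) == 2) {
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  }
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  round(arr * 255)
}

#' @rdname read_rgb
#' @param img A `height x width x 3` array, values 0-255.
#' @export
write_rgb <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
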