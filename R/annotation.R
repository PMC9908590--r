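#' Build a polygon region
#'
#' Regions are polygons in level-0 pixel coordinates (origin top-left,
#' x right, y down). The vertex list is stored open: the closing edge back
#' to the first vertex is implied, and serializers add the repeated vertex
#' that GeoJSON requires.
#'
#' @param id Caller-supplied stable region id (never renumbered).
#' @param polygon Numeric matrix with columns x, y and at least 3 rows.
#' @param layer `"decision"` or `"reason"`.
#' @param class_label Terminology class id.
#' @param subtype_label Optional terminology subtype id.
#' @param reason_labels Character vector of terminology reason ids; entries
#'   prefixed `"free:"` are free-text tokens outside the terminology.
#' @param pencil_shape One of `"curve"`, `"rectangle"`, `"brush"`.
#' @param free_text,voice_ref,created_ms Optional annotation metadata.
#' @return A one-row tibble in the region table layout.
#' @export
anno_region <- function(id, polygon, layer, class_label,
                        subtype_label = NA_character_,
                        reason_labels = character(),
                        pencil_shape = "curve",
                        free_text = NA_character_,
                        voice_ref = NA_character_,
                        created_ms = 0) {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  colnames(polygon) <- c("x", "y")
  tibble(
    id = as.character(id),
    layer = layer,
    pencil_shape = pencil_shape,
    class_label = as.character(class_label),
    subtype_label = as.character(subtype_label),
    reason_labels = list(as.character(reason_labels)),
    free_text = as.character(free_text),
    voice_ref = as.character(voice_ref),
    created_ms = as.numeric(created_ms),
    polygon = list(polygon)
  )
}

empty_region_table <- function() {
  tibble(
    id = character(), layer = character(), pencil_shape = character(),
    class_label = character(), subtype_label = character(),
    reason_labels = list(), free_text = character(), voice_ref = character(),
    created_ms = numeric(), polygon = list()
  )
}

empty_bundle_table <- function() {
  tibble(
    id = character(), member_region_ids = list(),
    caption_terms = list(), caption_diagnosis = character()
  )
}

#' Build a bundle row
#'
#' A bundle groups regions that share one caption, so an annotator can apply
#' a one-off description to many similar lesions.
#'
#' @param id Bundle id.
#' @param member_region_ids Character vector of member region ids (>= 1).
#' @param caption_terms Character vector of caption tokens: reason ids and/or
#'   `"free:"`-prefixed free-text tokens; at least one.
#' @param caption_diagnosis Optional subtype/class diagnosis phrase.
#' @return A one-row tibble in the bundle table layout.
#' @export
anno_bundle <- function(id, member_region_ids, caption_terms,
                        caption_diagnosis = NA_character_) {
  tibble(
    id = as.character(id),
    member_region_ids = list(as.character(member_region_ids)),
    caption_terms = list(as.character(caption_terms)),
    caption_diagnosis = as.character(caption_diagnosis)
  )
}

#' Assemble one slide's annotation document
#'
#' The document is hierarchical: decision-layer regions carry diagnosis
#' labels (class, optionally subtype), reason-layer regions carry the
#' morphological features justifying them, and bundles attach one caption to
#' several regions. A coarse-phase document holds only class-level decision
#' regions plus a slide-wise caption; the fine phase adds subtypes, reason
#' regions and bundles.
#'
#' @param wsi_id,annotator_id Identifiers.
#' @param phase `"coarse"` or `"fine"`.
#' @param width,height Slide size in level-0 pixels.
#' @param regions Region table (rows from [anno_region()]).
#' @param bundles Bundle table (rows from [anno_bundle()]).
#' @param slide_caption Free-text slide-wise diagnosis (coarse phase).
#' @param audit_status `"draft"`, `"submitted"` or `"audited"`.
#' @param events_ref Optional path to the behavioral trace for this session.
#' @return A `wsi_annotation` object.
#' @export
wsi_annotation <- function(wsi_id, annotator_id, phase, width, height,
                           regions = empty_region_table(),
                           bundles = empty_bundle_table(),
                           slide_caption = NA_character_,
                           audit_status = "draft",
                           events_ref = NA_character_) {
  structure(
    list(
      wsi_id = as.character(wsi_id),
      annotator_id = as.character(annotator_id),
      phase = phase,
      width = as.integer(width),
      height = as.integer(height),
      slide_caption = as.character(slide_caption),
      regions = as_tibble(regions),
      bundles = as_tibble(bundles),
      audit_status = audit_status,
      events_ref = as.character(events_ref)
    ),
    class = "wsi_annotation"
  )
}

#' @export
print.wsi_annotation <- function(x, ...) {
  cat(sprintf(
    "<wsi_annotation %s by %s: %s phase, %d regions, %d bundles, %s>\n",
    x$wsi_id, x$annotator_id, x$phase, nrow(x$regions), nrow(x$bundles),
    x$audit_status
  ))
  invisible(x)
}

is_free_token <- function(tok) startsWith(tok, "free:")

polygon_area <- function(p) {
  # shoelace; p open polygon matrix
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Validate an annotation document against a terminology
#'
#' Checks every structural invariant of the data model: unique region ids,
#' non-degenerate polygons, label lineage (subtype under its class, reasons
#' under the region's subtype unless flagged free-text), bundle membership,
#' phase discipline, and enum fields. Validation is pure: the document is
#' never modified.
#'
#' @param doc A [wsi_annotation()].
#' @param tree A [terminology_tree()].
#' @return A tibble of violations (`code`, `object_id`, `message`); zero rows
#'   means the document is valid.
#' @export
validate_annotation <- function(doc, tree) {
  if (!inherits(doc, "wsi_annotation")) {
    wsianno_abort("FORMAT_ERROR", "not a wsi_annotation object")
  }
  stopifnot(inherits(tree, "terminology_tree"))
  tb <- as_tibble(tree)
  v <- list()
  bad <- function(code, object_id, message) {
    v[[length(v) + 1]] <<- tibble(code = code, object_id = object_id, message = message)
  }

  if (!doc$phase %in% c("coarse", "fine")) {
    bad("PHASE_VIOLATION", doc$wsi_id, paste0("unknown phase '", doc$phase, "'"))
  }
  if (!doc$audit_status %in% c("draft", "submitted", "audited")) {
    bad("STATUS_VIOLATION", doc$wsi_id, paste0("unknown audit_status '", doc$audit_status, "'"))
  }

  rg <- doc$regions
  if (anyDuplicated(rg$id)) {
    for (d in unique(rg$id[duplicated(rg$id)])) {
      bad("DUPLICATE_REGION_ID", d, "region id appears more than once")
    }
  }
  level_of <- setNames(tb$level, tb$id)
  parent_of <- setNames(tb$parent_id, tb$id)

  for (k in seq_len(nrow(rg))) {
    r <- rg[k, ]
    p <- r$polygon[[1]]
    if (!is.matrix(p) || nrow(p) < 3) {
      bad("POLYGON_TOO_SMALL", r$id, "polygon needs at least 3 vertices")
    } else if (polygon_area(p) == 0) {
      bad("DEGENERATE_POLYGON", r$id, "polygon has zero area")
    }
    if (!r$layer %in% c("decision", "reason")) {
      bad("LAYER_VIOLATION", r$id, paste0("unknown layer '", r$layer, "'"))
    }
    if (!r$pencil_shape %in% c("curve", "rectangle", "brush")) {
      bad("PENCIL_VIOLATION", r$id, paste0("unknown pencil_shape '", r$pencil_shape, "'"))
    }
    if (is.na(level_of[r$class_label]) || level_of[r$class_label] != "class") {
      bad("LABEL_UNKNOWN", r$id, paste0("class_label '", r$class_label, "' is not a terminology class"))
    }
    if (!is.na(r$subtype_label)) {
      if (is.na(level_of[r$subtype_label]) || level_of[r$subtype_label] != "subtype") {
        bad("LABEL_UNKNOWN", r$id, paste0("subtype_label '", r$subtype_label, "' is not a terminology subtype"))
      } else if (parent_of[r$subtype_label] != r$class_label) {
        bad("LABEL_LINEAGE", r$id, paste0(
          "subtype '", r$subtype_label, "' is not a child of class '", r$class_label, "'"
        ))
      }
    }
    rl <- r$reason_labels[[1]]
    rl <- rl[!is_free_token(rl)]
    for (lab in rl) {
      if (is.na(level_of[lab]) || level_of[lab] != "reason") {
        bad("LABEL_UNKNOWN", r$id, paste0("reason label '", lab, "' is not a terminology reason entry"))
        next
      }
      if (!is.na(r$subtype_label)) {
        anc <- term_ancestors(tree, lab)
        if (!(r$subtype_label %in% anc)) {
          bad("LABEL_LINEAGE", r$id, paste0(
            "reason '", lab, "' does not descend from subtype '", r$subtype_label, "'"
          ))
        }
      }
    }
    if (length(r$reason_labels[[1]]) > 0 && r$layer == "decision" && doc$phase == "coarse") {
      bad("PHASE_VIOLATION", r$id, "coarse-phase regions carry no reason labels")
    }
  }

  if (doc$phase == "coarse") {
    off <- rg$id[rg$layer != "decision" | !is.na(rg$subtype_label)]
    for (i in off) {
      bad("PHASE_VIOLATION", i, "coarse-phase documents contain only class-level decision regions")
    }
    if (is.na(doc$slide_caption) || !nzchar(doc$slide_caption)) {
      bad("PHASE_VIOLATION", doc$wsi_id, "coarse-phase documents need a slide caption")
    }
  }

  bd <- doc$bundles
  seen_members <- character()
  for (k in seq_len(nrow(bd))) {
    b <- bd[k, ]
    mem <- b$member_region_ids[[1]]
    if (length(mem) < 1) {
      bad("EMPTY_BUNDLE", b$id, "bundle has no members")
    }
    miss <- setdiff(mem, rg$id)
    for (m in miss) {
      bad("DANGLING_BUNDLE_MEMBER", b$id, paste0("bundle references missing region '", m, "'"))
    }
    dup <- intersect(mem, seen_members)
    for (m in dup) {
      bad("AMBIGUOUS_BUNDLE", b$id, paste0("region '", m, "' belongs to more than one bundle"))
    }
    seen_members <- c(seen_members, mem)
    if (length(b$caption_terms[[1]]) < 1) {
      bad("EMPTY_CAPTION", b$id, "bundle caption needs at least one term")
    }
  }

  if (length(v) == 0) {
    tibble(code = character(), object_id = character(), message = character())
  } else {
    bind_rows(v)
  }
}

#' Expand bundles into per-region captions
#'
#' Each bundle contributes its caption once per member region; reason-layer
#' regions outside every bundle contribute their own reason labels as a
#' caption. Every reason-layer region is covered exactly once.
#'
#' @param doc A valid [wsi_annotation()].
#' @return A tibble (`region_id`, `terms` list-column, `diagnosis_phrase`,
#'   `bundle_id`; `bundle_id` is `NA` for unbundled regions).
#' @export
expand_bundles <- function(doc) {
  stopifnot(inherits(doc, "wsi_annotation"))
  bd <- doc$bundles
  all_members <- unlist(bd$member_region_ids)
  if (anyDuplicated(all_members)) {
    wsianno_abort("AMBIGUOUS_BUNDLE", paste0(
      "region(s) in more than one bundle: ",
      paste(unique(all_members[duplicated(all_members)]), collapse = ", ")
    ))
  }
  out <- list()
  for (k in seq_len(nrow(bd))) {
    for (m in bd$member_region_ids[[k]]) {
      out[[length(out) + 1]] <- tibble(
        region_id = m, terms = bd$caption_terms[k],
        diagnosis_phrase = bd$caption_diagnosis[k], bundle_id = bd$id[k]
      )
    }
  }
  free <- doc$regions %>%
    filter(.data$layer == "reason", !(.data$id %in% all_members))
  for (k in seq_len(nrow(free))) {
    out[[length(out) + 1]] <- tibble(
      region_id = free$id[k], terms = free$reason_labels[k],
      diagnosis_phrase = NA_character_, bundle_id = NA_character_
    )
  }
  if (length(out) == 0) {
    return(tibble(
      region_id = character(), terms = list(),
      diagnosis_phrase = character(), bundle_id = character()
    ))
  }
  bind_rows(out)
}

#' Caption and annotation statistics over a cohort
#'
#' @param docs A list of [wsi_annotation()] documents.
#' @return A one-row tibble: mean/max/min caption term counts, and mean
#'   captions, regions and bundles per slide. Captions are the
#'   [expand_bundles()] output, so a bundled caption counts once per slide
#'   per distinct caption unit, matching how captions are authored.
#' @export
caption_stats <- function(docs) {
  if (length(docs) == 0) {
    wsianno_abort("EMPTY_COHORT", "caption_stats needs at least one document")
  }
  per_doc <- map(docs, function(d) {
    ex <- expand_bundles(d)
    # one caption unit per bundle + one per unbundled reason region
    units <- bind_rows(
      ex %>% filter(!is.na(.data$bundle_id)) %>% distinct(.data$bundle_id, .keep_all = TRUE),
      ex %>% filter(is.na(.data$bundle_id))
    )
    tibble(
      wsi_id = d$wsi_id,
      n_captions = nrow(units),
      n_regions = nrow(d$regions),
      n_bundles = nrow(d$bundles),
      term_counts = list(lengths(units$terms))
    )
  }) %>% bind_rows()
  counts <- unlist(per_doc$term_counts)
  if (length(counts) == 0) {
    wsianno_abort("EMPTY_COHORT", "cohort contains no captions")
  }
  tibble(
    mean_terms_per_caption = mean(counts),
    max_terms_per_caption = max(counts),
    min_terms_per_caption = min(counts),
    se_terms_per_caption = sd(counts) / sqrt(length(counts)),
    n_captions = length(counts),
    captions_per_wsi = mean(per_doc$n_captions),
    regions_per_wsi = mean(per_doc$n_regions),
    bundles_per_wsi = mean(per_doc$n_bundles)
  )
}

#' Slide-level class of a document
#'
#' The slide class is the highest-severity class present among decision
#' regions (adenocarcinoma > adenoma > normal); a document without tumor
#' regions is normal.
#'
#' @param doc A [wsi_annotation()].
#' @param priority Classes ordered most to least severe (terminology class
#'   ids as used in the document).
#' @return A single class id.
#' @export
slide_class <- function(doc, priority = c("c_adenocarcinoma", "c_adenoma", "c_normal")) {
  present <- unique(doc$regions$class_label[doc$regions$layer == "decision"])
  for (p in priority) if (p %in% present) return(p)
  tail(priority, 1)
}
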