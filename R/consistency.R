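#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement over parallel categorical label vectors:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' fraction and `p_e = sum_k marginal_a(k) * marginal_b(k)`. When both
#' raters are constant and identical `p_e = 1`; that degenerate case is
#' reported as `kappa = 1` with a flag rather than 0/0.
#'
#' @param labels_a,labels_b Parallel label vectors (equal length, >= 1).
#' @return One-row tibble: `kappa`, `p_o`, `p_e`, `n`, `degenerate`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    wsianno_abort("FORMAT_ERROR", "label vectors differ in length")
  }
  n <- length(labels_a)
  if (n < 1) {
    wsianno_abort("EMPTY_COHORT", "kappa needs at least one unit")
  }
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  K <- sort(unique(c(labels_a, labels_b)))
  p_o <- mean(labels_a == labels_b)
  ma <- table(factor(labels_a, levels = K)) / n
  mb <- table(factor(labels_b, levels = K)) / n
  p_e <- sum(as.numeric(ma) * as.numeric(mb))
  degenerate <- p_e >= 1 - 1e-12
  kappa <- if (degenerate) 1 else (p_o - p_e) / (1 - p_e)
  tibble(kappa = kappa, p_o = p_o, p_e = p_e, n = n, degenerate = degenerate)
}

#' Dice coefficient between two binary masks
#'
#' `2|A . B| / (|A| + |B|)`; two empty masks are reported as Dice 1 with a
#' flag (perfect agreement on absence).
#'
#' @param mask_a,mask_b Logical (or 0/1) arrays of identical shape.
#' @return One-row tibble: `dice`, `size_a`, `size_b`, `overlap`, `empty`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a) %||% length(mask_a), dim(mask_b) %||% length(mask_b))) {
    wsianno_abort("FORMAT_ERROR", "mask shapes differ")
  }
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  sa <- sum(a); sb <- sum(b); ov <- sum(a & b)
  empty <- (sa + sb) == 0
  tibble(
    dice = if (empty) 1 else 2 * ov / (sa + sb),
    size_a = sa, size_b = sb, overlap = ov, empty = empty
  )
}

#' Per-label Dice between two label maps
#'
#' @param map_a,map_b Label matrices (NA = unlabeled background).
#' @param labels Label set to evaluate; defaults to all labels present.
#' @return Tibble (`label`, `dice`, `size_a`, `size_b`, `overlap`, `empty`).
#' @export
per_label_dice <- function(map_a, map_b, labels = NULL) {
  if (!identical(dim(map_a), dim(map_b))) {
    wsianno_abort("FORMAT_ERROR", "label map shapes differ")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(map_a[!is.na(map_a)], map_b[!is.na(map_b)])))
  }
  bind_rows(lapply(labels, function(l) {
    dice_coefficient(!is.na(map_a) & map_a == l, !is.na(map_b) & map_b == l) %>%
      mutate(label = l, .before = 1)
  }))
}

# ---- BLEU ------------------------------------------------------------------

#' Tokenize a caption for BLEU scoring
#'
#' Lowercases, splits on whitespace and commas, and strips trailing periods.
#' Terminology-id tokens are detokenized to their display names first when a
#' tree is supplied, so captions written with ids and captions written with
#' words score identically.
#'
#' @param caption Character scalar or vector of tokens (terminology ids,
#'   `"free:"` tokens, or plain words).
#' @param tree Optional [terminology_tree()] for id detokenization.
#' @return Character vector of tokens.
#' @export
tokenize_caption <- function(caption, tree = NULL) {
  toks <- unlist(lapply(caption, function(tok) {
    if (!is.null(tree) && tok %in% as_tibble(tree)$id) {
      as_tibble(tree)$name[as_tibble(tree)$id == tok]
    } else if (is_free_token(tok)) {
      sub("^free:", "", tok)
    } else {
      tok
    }
  }))
  toks <- unlist(strsplit(tolower(toks), "[,[:space:]]+"))
  toks <- gsub("\\.+$", "", toks)
  toks[nzchar(toks)]
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character())
  vapply(seq_len(length(tokens) - n + 1),
         function(i) paste(tokens[i:(i + n - 1)], collapse = ""),
         character(1))
}

#' Clipped n-gram precision (one BLEU order)
#'
#' `sum_g Count_clip(g) / sum_g Count(g)` over the candidate's n-grams,
#' where each n-gram's count is clipped at its maximum count in any
#' reference. A candidate shorter than `n` scores 0 (flagged).
#'
#' @param candidate Token vector of the candidate caption.
#' @param references List of reference token vectors (or one vector).
#' @param n N-gram order (>= 1).
#' @return One-row tibble: `n`, `precision`, `clipped`, `total`, `short`.
#' @export
bleu_n <- function(candidate, references, n) {
  stopifnot(n >= 1)
  if (length(candidate) == 0) {
    wsianno_abort("EMPTY_CAPTION", "candidate caption has no tokens")
  }
  if (!is.list(references)) references <- list(references)
  cand_ng <- ngrams(candidate, n)
  if (length(cand_ng) == 0) {
    return(tibble(n = n, precision = 0, clipped = 0L, total = 0L, short = TRUE))
  }
  cand_counts <- table(cand_ng)
  ref_max <- numeric(length(cand_counts))
  names(ref_max) <- names(cand_counts)
  for (ref in references) {
    rc <- table(ngrams(ref, n))
    shared <- intersect(names(rc), names(ref_max))
    ref_max[shared] <- pmax(ref_max[shared], as.numeric(rc[shared]))
  }
  clipped <- sum(pmin(as.numeric(cand_counts), ref_max))
  total <- sum(cand_counts)
  tibble(n = n, precision = clipped / total,
         clipped = as.integer(clipped), total = as.integer(total), short = FALSE)
}

#' Composite BLEU score
#'
#' Brevity penalty times the geometric mean of clipped n-gram precisions of
#' orders `1..max_n`. Default is unsmoothed: any zero precision gives BLEU
#' 0, and BLEU equals 1 exactly when candidate and reference match.
#' `smoothing = "epsilon"` replaces zero precisions with a small constant.
#'
#' @inheritParams bleu_n
#' @param max_n Highest n-gram order (default 4).
#' @param smoothing `"none"` (default) or `"epsilon"`.
#' @param eps Epsilon for `smoothing = "epsilon"`.
#' @return One-row tibble: `bleu`, `brevity_penalty`, and `p1..p{max_n}`.
#' @export
bleu_composite <- function(candidate, references, max_n = 4,
                           smoothing = c("none", "epsilon"), eps = 1e-9) {
  smoothing <- match.arg(smoothing)
  if (!is.list(references)) references <- list(references)
  precisions <- vapply(
    seq_len(max_n),
    function(n) bleu_n(candidate, references, n)$precision,
    numeric(1)
  )
  if (smoothing == "epsilon") precisions[precisions == 0] <- eps
  c_len <- length(candidate)
  # closest reference length (standard brevity penalty)
  ref_lens <- vapply(references, length, integer(1))
  r_len <- ref_lens[which.min(abs(ref_lens - c_len))]
  bp <- if (c_len > r_len) 1 else exp(1 - r_len / c_len)
  bleu <- if (any(precisions == 0)) 0 else bp * exp(mean(log(precisions)))
  out <- tibble(bleu = bleu, brevity_penalty = bp)
  for (n in seq_len(max_n)) out[[paste0("p", n)]] <- precisions[n]
  out
}

# ---- polygon rasterization and IoU ----------------------------------------

# label map of decision (or reason) regions at a downsample; later regions
# never overwrite higher-priority earlier labels
rasterize_regions <- function(regions, width, height, downsample = 4,
                              priority = c("c_adenocarcinoma", "c_adenoma", "c_normal"),
                              label_col = "class_label") {
  w <- ceiling(width / downsample); h <- ceiling(height / downsample)
  out <- matrix(NA_character_, nrow = h, ncol = w)
  rank <- matrix(Inf, nrow = h, ncol = w)
  xs <- (seq_len(w) - 0.5) * downsample
  ys <- (seq_len(h) - 0.5) * downsample
  for (k in seq_len(nrow(regions))) {
    lab <- regions[[label_col]][k]
    if (is.na(lab)) next
    r <- match(lab, priority)
    if (is.na(r)) r <- length(priority) + 1
    p <- regions$polygon[[k]]
    inside <- polygon_raster_mask(p, xs, ys)
    idx <- which(inside, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    better <- r < rank[idx]
    idx <- idx[better, , drop = FALSE]
    out[idx] <- lab
    rank[idx] <- r
  }
  out
}

polygon_iou <- function(poly_a, poly_b, downsample = 4) {
  xr <- range(c(poly_a[, 1], poly_b[, 1]))
  yr <- range(c(poly_a[, 2], poly_b[, 2]))
  xs <- seq(xr[1] + downsample / 2, xr[2], by = downsample)
  ys <- seq(yr[1] + downsample / 2, yr[2], by = downsample)
  if (length(xs) == 0 || length(ys) == 0) return(0)
  in_a <- polygon_raster_mask(poly_a, xs, ys)
  in_b <- polygon_raster_mask(poly_b, xs, ys)
  un <- sum(in_a | in_b)
  if (un == 0) return(0)
  sum(in_a & in_b) / un
}

# ---- document comparison ---------------------------------------------------

#' Multi-level agreement between two annotations of one slide
#'
#' Computes the three-level consistency protocol: slide-level class
#' agreement, patch-level Cohen's kappa over central-pixel labels on a
#' shared grid (class labels and subtype labels separately), pixel-level
#' Dice per shared label on rasterized regions, and BLEU-1 between captions
#' of regions paired by polygon IoU. By default patches unlabeled by both
#' annotators are excluded from kappa (the both-background class would
#' inflate agreement); set `include_background = TRUE` to keep them as an
#' explicit background label.
#'
#' @param doc_a,doc_b Two [wsi_annotation()] documents for the same slide.
#' @param grid A [patch_grid()] for the patch level.
#' @param downsample Linear downsample for pixel-level rasterization.
#' @param include_background Keep both-unlabeled patches in kappa.
#' @param tree Optional terminology for caption detokenization.
#' @param iou_threshold Minimum IoU to pair reason regions for BLEU.
#' @return An `agreement_report` list: `wsi` (slide classes and agreement),
#'   `patch_class`, `patch_subtype` (kappa rows), `pixel_dice` (per-label
#'   tibble), `captions` (paired-region BLEU-1 tibble), `bleu1_mean`.
#' @export
compare_annotations <- function(doc_a, doc_b, grid = patch_grid(),
                                downsample = 4, include_background = FALSE,
                                tree = NULL, iou_threshold = 0.25) {
  if (!identical(doc_a$wsi_id, doc_b$wsi_id)) {
    wsianno_abort("FORMAT_ERROR", "documents describe different slides")
  }
  W <- max(doc_a$width, doc_b$width); H <- max(doc_a$height, doc_b$height)

  wsi_level <- tibble(
    class_a = slide_class(doc_a), class_b = slide_class(doc_b)
  ) %>% mutate(agree = .data$class_a == .data$class_b)

  # patch level: central-pixel labels on the shared grid
  ps <- grid$patch_size; st <- grid$stride
  is <- 0:max(0, floor((W - ps) / st))
  js <- 0:max(0, floor((H - ps) / st))
  centers <- tidyr::expand_grid(i = is, j = js) %>%
    mutate(cx = .data$i * st + ps / 2, cy = .data$j * st + ps / 2)
  lab_a <- bind_rows(map2(centers$cx, centers$cy,
                          ~ assign_patch_label(c(.x, .y), doc_a$regions)))
  lab_b <- bind_rows(map2(centers$cx, centers$cy,
                          ~ assign_patch_label(c(.x, .y), doc_b$regions)))
  kappa_level <- function(a, b) {
    keep <- !(is.na(a) & is.na(b))
    if (include_background) keep <- rep(TRUE, length(a))
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) {
      return(tibble(kappa = NA_real_, p_o = NA_real_, p_e = NA_real_,
                    n = 0L, degenerate = FALSE))
    }
    cohen_kappa(ifelse(is.na(a), ".background", a),
                ifelse(is.na(b), ".background", b))
  }
  patch_class <- kappa_level(lab_a$label_class, lab_b$label_class)
  patch_subtype <- kappa_level(lab_a$label_subtype, lab_b$label_subtype)

  # pixel level: per-label Dice on rasterized decision regions
  ra <- rasterize_regions(doc_a$regions[doc_a$regions$layer == "decision", ], W, H, downsample)
  rb <- rasterize_regions(doc_b$regions[doc_b$regions$layer == "decision", ], W, H, downsample)
  pixel_dice <- per_label_dice(ra, rb)

  # caption level: pair reason regions by IoU, score BLEU-1
  reasons_a <- doc_a$regions %>% filter(.data$layer == "reason")
  reasons_b <- doc_b$regions %>% filter(.data$layer == "reason")
  cap_a <- expand_bundles(doc_a); cap_b <- expand_bundles(doc_b)
  pairs <- list()
  if (nrow(reasons_a) > 0 && nrow(reasons_b) > 0) {
    iou <- matrix(0, nrow(reasons_a), nrow(reasons_b))
    for (i in seq_len(nrow(reasons_a))) {
      for (j in seq_len(nrow(reasons_b))) {
        iou[i, j] <- polygon_iou(reasons_a$polygon[[i]], reasons_b$polygon[[j]], downsample)
      }
    }
    taken_b <- logical(nrow(reasons_b))
    ord <- order(iou, decreasing = TRUE)
    for (o in ord) {
      if (iou[o] < iou_threshold) break
      i <- (o - 1) %% nrow(reasons_a) + 1
      j <- (o - 1) %/% nrow(reasons_a) + 1
      if (any(vapply(pairs, function(p) p$i == i, logical(1))) || taken_b[j]) next
      taken_b[j] <- TRUE
      pairs[[length(pairs) + 1]] <- list(i = i, j = j, iou = iou[o])
    }
  }
  captions <- bind_rows(lapply(pairs, function(p) {
    ta <- cap_a$terms[cap_a$region_id == reasons_a$id[p$i]]
    tb <- cap_b$terms[cap_b$region_id == reasons_b$id[p$j]]
    if (length(ta) == 0 || length(tb) == 0) return(NULL)
    toks_a <- tokenize_caption(ta[[1]], tree)
    toks_b <- tokenize_caption(tb[[1]], tree)
    if (length(toks_a) == 0 || length(toks_b) == 0) return(NULL)
    tibble(
      region_a = reasons_a$id[p$i], region_b = reasons_b$id[p$j],
      iou = p$iou, bleu1 = bleu_n(toks_a, list(toks_b), 1)$precision
    )
  }))
  structure(
    list(
      wsi_id = doc_a$wsi_id,
      wsi = wsi_level,
      patch_class = patch_class,
      patch_subtype = patch_subtype,
      pixel_dice = pixel_dice,
      captions = captions,
      bleu1_mean = if (nrow(captions) > 0) mean(captions$bleu1) else NA_real_
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report %s: slide %s, patch kappa %.3f (class) / %.3f (subtype), mean Dice %.3f, mean BLEU1 %s>\n",
    x$wsi_id,
    if (isTRUE(x$wsi$agree)) "agree" else "disagree",
    x$patch_class$kappa, x$patch_subtype$kappa,
    mean(x$pixel_dice$dice),
    if (is.na(x$bleu1_mean)) "NA" else sprintf("%.3f", x$bleu1_mean)
  ))
  invisible(x)
}

# ---- audit diff ------------------------------------------------------------

#' Structural diff between two annotation versions
#'
#' Matches regions greedily by descending polygon IoU (threshold 0.5);
#' unmatched old regions are removals, unmatched new ones additions, and
#' matched regions with different labels or captions are modifications.
#' Formalizes the senior-pathologist audit pass as a reproducible report.
#'
#' @param old_doc,new_doc Two [wsi_annotation()] versions of one slide.
#' @param iou_threshold Minimum IoU to consider regions the same lesion.
#' @param downsample Raster downsample for IoU computation.
#' @return An `audit_report`: tibbles `added`, `removed`, `modified`
#'   (`old_id`, `new_id`, `what` in label/subtype/caption), `matched`.
#' @export
audit_diff <- function(old_doc, new_doc, iou_threshold = 0.5, downsample = 4) {
  if (!identical(old_doc$wsi_id, new_doc$wsi_id)) {
    wsianno_abort("FORMAT_ERROR", "documents describe different slides")
  }
  ro <- old_doc$regions; rn <- new_doc$regions
  matched <- tibble(old_id = character(), new_id = character(), iou = numeric())
  if (nrow(ro) > 0 && nrow(rn) > 0) {
    iou <- matrix(0, nrow(ro), nrow(rn))
    for (i in seq_len(nrow(ro))) {
      for (j in seq_len(nrow(rn))) {
        if (ro$layer[i] != rn$layer[j]) next
        iou[i, j] <- polygon_iou(ro$polygon[[i]], rn$polygon[[j]], downsample)
      }
    }
    used_o <- logical(nrow(ro)); used_n <- logical(nrow(rn))
    for (o in order(iou, decreasing = TRUE)) {
      if (iou[o] < iou_threshold) break
      i <- (o - 1) %% nrow(ro) + 1
      j <- (o - 1) %/% nrow(ro) + 1
      if (used_o[i] || used_n[j]) next
      used_o[i] <- TRUE; used_n[j] <- TRUE
      matched <- bind_rows(matched, tibble(old_id = ro$id[i], new_id = rn$id[j], iou = iou[o]))
    }
  }
  cap_o <- expand_bundles(old_doc); cap_n <- expand_bundles(new_doc)
  caption_of <- function(cap, id) {
    t <- cap$terms[cap$region_id == id]
    if (length(t) == 0) character() else t[[1]]
  }
  mods <- list()
  for (k in seq_len(nrow(matched))) {
    i <- match(matched$old_id[k], ro$id); j <- match(matched$new_id[k], rn$id)
    what <- character()
    if (!identical(ro$class_label[i], rn$class_label[j])) what <- c(what, "label")
    if (!identical(ro$subtype_label[i], rn$subtype_label[j])) what <- c(what, "subtype")
    if (!identical(caption_of(cap_o, ro$id[i]), caption_of(cap_n, rn$id[j]))) {
      what <- c(what, "caption")
    }
    if (length(what) > 0) {
      mods[[length(mods) + 1]] <- tibble(
        old_id = ro$id[i], new_id = rn$id[j], what = paste(what, collapse = "+")
      )
    }
  }
  structure(
    list(
      wsi_id = old_doc$wsi_id,
      added = rn %>% filter(!(.data$id %in% matched$new_id)) %>% select("id", "layer", "class_label"),
      removed = ro %>% filter(!(.data$id %in% matched$old_id)) %>% select("id", "layer", "class_label"),
      modified = if (length(mods) > 0) bind_rows(mods) else
        tibble(old_id = character(), new_id = character(), what = character()),
      matched = matched
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf(
    "<audit_report %s: %d added, %d removed, %d modified, %d unchanged>\n",
    x$wsi_id, nrow(x$added), nrow(x$removed), nrow(x$modified),
    nrow(x$matched) - nrow(x$modified)
  ))
  invisible(x)
}

# ---- confusion matrix ------------------------------------------------------

#' Build a confusion matrix object
#'
#' @param counts K x K non-negative integer matrix, rows = ground truth,
#'   columns = prediction.
#' @param labels Ordered label names.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(counts)))
  stopifnot(nrow(counts) == ncol(counts), length(labels) == nrow(counts))
  if (any(counts < 0) || sum(counts) == 0) {
    wsianno_abort("FORMAT_ERROR", "confusion matrix needs non-negative counts with positive total")
  }
  dimnames(counts) <- list(truth = labels, prediction = labels)
  structure(list(counts = counts, labels = labels), class = "confusion_matrix")
}

#' Per-class recall/precision and overall accuracy
#'
#' `recall_k = cm[k,k] / rowsum_k`, `precision_k = cm[k,k] / colsum_k`,
#' `accuracy = trace / total`. Zero denominators yield `NA` (undefined), not
#' zero.
#'
#' @param cm A [confusion_matrix()].
#' @return A `classification_report`: list with `per_class` tibble
#'   (`label`, `recall`, `precision`, `support`) and `accuracy`.
#' @export
classification_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  rs <- unname(rowSums(m)); cs <- unname(colSums(m)); d <- unname(diag(m))
  per_class <- tibble(
    label = cm$labels,
    recall = ifelse(rs > 0, d / rs, NA_real_),
    precision = ifelse(cs > 0, d / cs, NA_real_),
    support = as.integer(rs)
  )
  structure(
    list(per_class = per_class, accuracy = sum(d) / sum(m), n = sum(m)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report: accuracy %.2f%% on %d units>\n",
              100 * x$accuracy, x$n))
  print(x$per_class)
  invisible(x)
}

#' Read / write a labeled confusion matrix as CSV
#'
#' CSV with a header row of prediction labels and a first column of truth
#' labels.
#'
#' @param cm A [confusion_matrix()].
#' @param path File path.
#' @return `read_confusion_csv` returns a [confusion_matrix()].
#' @export
write_confusion_csv <- function(cm, path) {
  df <- as.data.frame(cm$counts)
  df <- cbind(truth = cm$labels, df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    truth = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$truth
  confusion_matrix(m, labels = df$truth)
}
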