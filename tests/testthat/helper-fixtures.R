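# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms from the implementation they check.

tiny_tree <- function() {
  terminology_tree(tibble::tibble(
    id = c("c_adenocarcinoma", "c_adenoma", "c_normal",
           "s_ca1", "s_ca2", "s_ad1", "s_nm1",
           "r_ca1", "r_ca2", "r_ca3", "r_ad1", "r_nm1"),
    level = c(rep("class", 3), rep("subtype", 4), rep("reason", 5)),
    parent_id = c(NA, NA, NA,
                  "c_adenocarcinoma", "c_adenocarcinoma", "c_adenoma", "c_normal",
                  "s_ca1", "s_ca1", "s_ca2", "s_ad1", "s_nm1"),
    name = c("Adenocarcinoma", "Adenoma", "Normal",
             "Poorly differentiated", "Tumor invasion", "Low-grade adenoma", "Normal",
             "Cribriform structure", "Necrosis", "Tumor budding grade 1",
             "Tubular structure", "Smooth muscle"),
    order = c(1:3, 1, 2, 1, 1, 1, 2, 1, 1, 1)
  ))
}

square_poly <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side, x0 + side, x0),
        y = c(y0, y0, y0 + side, y0 + side))
}

# a small valid fine-phase document on a 256x256 slide
tiny_doc <- function(wsi_id = "w1") {
  regions <- dplyr::bind_rows(
    anno_region("d1", square_poly(20, 20, 100), "decision",
                "c_adenocarcinoma", "s_ca1"),
    anno_region("d2", square_poly(150, 150, 80), "decision",
                "c_adenoma", "s_ad1"),
    anno_region("r1", square_poly(30, 30, 40), "reason",
                "c_adenocarcinoma", "s_ca1", reason_labels = c("r_ca1", "r_ca2")),
    anno_region("r2", square_poly(75, 40, 30), "reason",
                "c_adenocarcinoma", "s_ca1", reason_labels = "r_ca2"),
    anno_region("r3", square_poly(160, 160, 30), "reason",
                "c_adenoma", "s_ad1", reason_labels = "r_ad1")
  )
  bundles <- anno_bundle("b1", c("r1", "r2"), c("r_ca1", "r_ca2"),
                         caption_diagnosis = "Poorly differentiated")
  wsi_annotation(wsi_id, "annotA", "fine", 256, 256,
                 regions = regions, bundles = bundles,
                 slide_caption = "tumor slide")
}

# random valid document for property tests (seeded by caller)
random_doc <- function(wsi_id, tree = tiny_tree(), n_decision = 3, n_reason = 4) {
  tb <- tibble::as_tibble(tree)
  classes <- tb$id[tb$level == "class"]
  regions <- empty_region_table <- NULL
  rows <- list()
  for (k in seq_len(n_decision)) {
    cls <- sample(classes, 1)
    subs <- tb$id[tb$level == "subtype" & tb$parent_id == cls]
    rows[[length(rows) + 1]] <- anno_region(
      paste0("d", k), square_poly(sample(0:150, 1), sample(0:150, 1), sample(20:60, 1)),
      "decision", cls, sample(subs, 1)
    )
  }
  reason_ids <- character()
  for (k in seq_len(n_reason)) {
    cls <- sample(classes, 1)
    subs <- tb$id[tb$level == "subtype" & tb$parent_id == cls]
    sub <- sample(subs, 1)
    reasons <- tb$id[tb$level == "reason" & tb$parent_id == sub]
    rows[[length(rows) + 1]] <- anno_region(
      paste0("r", k), square_poly(sample(0:180, 1), sample(0:180, 1), sample(10:40, 1)),
      "reason", cls, sub,
      reason_labels = sample(reasons, sample(1:2, 1), replace = TRUE)
    )
    reason_ids <- c(reason_ids, paste0("r", k))
  }
  n_bundled <- sample(0:min(2, length(reason_ids) %/% 2), 1)
  bundles <- NULL
  if (n_bundled > 0) {
    picked <- sample(reason_ids, 2 * n_bundled)
    bundles <- dplyr::bind_rows(lapply(seq_len(n_bundled), function(b) {
      anno_bundle(paste0("b", b), picked[(2 * b - 1):(2 * b)],
                  sample(tb$id[tb$level == "reason"], 2))
    }))
  }
  wsi_annotation(wsi_id, "annotR", "fine", 256, 256,
                 regions = dplyr::bind_rows(rows),
                 bundles = if (is.null(bundles)) {
                   tibble::tibble(id = character(), member_region_ids = list(),
                                  caption_terms = list(), caption_diagnosis = character())
                 } else bundles,
                 slide_caption = "random doc")
}

# --- independent oracles ----------------------------------------------------

# Otsu by exhaustive search over all 255 splits, straight from the
# between-class-variance definition
otsu_oracle <- function(h) {
  total <- sum(h)
  lv <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lv[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * lv[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-9) { best_v <- v; best_t <- t }
  }
  best_t
}

# winding-number point-in-polygon (nonzero rule; agrees with even-odd for
# simple polygons, which is what the toolkit guarantees off-boundary)
winding_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    wn <- 0
    for (e in seq_len(n)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      e2 <- if (e == n) 1 else e + 1
      x2 <- poly[e2, 1]; y2 <- poly[e2, 2]
      if (y1 <= y) {
        if (y2 > y && (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1) > 0) wn <- wn + 1
      } else {
        if (y2 <= y && (x2 - x1) * (y - y1) - (x - x1) * (y2 - y1) < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# textbook Cohen's kappa via the full contingency table
kappa_oracle <- function(a, b) {
  K <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = K), factor(b, levels = K))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# brute-force clipped n-gram precision by explicit enumeration
bleu_oracle <- function(cand, refs, n) {
  if (!is.list(refs)) refs <- list(refs)
  if (length(cand) < n) return(0)
  cand_ngrams <- sapply(seq_len(length(cand) - n + 1),
                        function(i) paste(cand[i:(i + n - 1)], collapse = "\r"))
  clip_total <- 0
  for (g in unique(cand_ngrams)) {
    cnt <- sum(cand_ngrams == g)
    ref_best <- 0
    for (ref in refs) {
      if (length(ref) < n) next
      rg <- sapply(seq_len(length(ref) - n + 1),
                   function(i) paste(ref[i:(i + n - 1)], collapse = "\r"))
      ref_best <- max(ref_best, sum(rg == g))
    }
    clip_total <- clip_total + min(cnt, ref_best)
  }
  clip_total / length(cand_ngrams)
}
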