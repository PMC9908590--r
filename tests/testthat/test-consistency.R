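test_that("Cohen's kappa matches hand evaluation and the contingency oracle", {
  # identical lists
  expect_equal(cohen_kappa(c("A", "B", "A"), c("A", "B", "A"))$kappa, 1)
  # hand-evaluated worked example
  k <- cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.5)
  # random pairs vs the independent contingency-table formula
  set.seed(41)
  for (r in 1:40) {
    n <- sample(5:200, 1)
    K <- sample(2:5, 1)
    a <- sample(letters[1:K], n, replace = TRUE)
    b <- sample(letters[1:K], n, replace = TRUE)
    if (sum(a == b) == n) next
    expect_equal(cohen_kappa(a, b)$kappa, kappa_oracle(a, b), tolerance = 1e-12)
  }
  # degenerate constant agreement
  kd <- cohen_kappa(rep("x", 5), rep("x", 5))
  expect_equal(kd$kappa, 1)
  expect_true(kd$degenerate)
  expect_error(cohen_kappa(character(), character()), class = "wsianno_empty_cohort")
  expect_error(cohen_kappa("a", c("a", "b")), class = "wsianno_format_error")
})

test_that("kappa is invariant under label renaming, bounded, and zero in expectation under shuffles", {
  set.seed(43)
  a <- sample(c("x", "y", "z"), 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  b <- ifelse(runif(300) < 0.7, a, sample(c("x", "y", "z"), 300, replace = TRUE))
  k1 <- cohen_kappa(a, b)$kappa
  ren <- c(x = "label_1", y = "label_2", z = "label_3")
  expect_equal(cohen_kappa(ren[a], ren[b])$kappa, k1)
  expect_lte(k1, 1)
  # Monte-Carlo: shuffled rater has expected kappa 0
  ks <- vapply(1:200, function(i) cohen_kappa(a, sample(b))$kappa, numeric(1))
  expect_lt(abs(mean(ks)), 3 * sd(ks) / sqrt(length(ks)) + 1e-3)
  expect_true(all(ks <= 1))
})

test_that("Dice behaves as an overlap measure", {
  m <- matrix(FALSE, 4, 4)
  a <- m; a[1:2, 1:2] <- TRUE                   # |A| = 4
  b <- m; b[1, 1:2] <- TRUE; b[2, 1] <- TRUE    # 3 cells shared with A ...
  b[3:4, 1] <- TRUE; b[4, 4] <- TRUE            # ... plus 3 of its own: |B| = 6
  expect_equal(dice_coefficient(a, a)$dice, 1)
  expect_equal(dice_coefficient(a, !a)$dice, 0)
  d <- dice_coefficient(a, b)
  expect_equal(d$dice, 2 * 3 / (4 + 6))
  # hand formula cross-check
  expect_equal(d$dice, 2 * sum(a & b) / (sum(a) + sum(b)))
  # empty-vs-empty flagged as perfect
  de <- dice_coefficient(m, m)
  expect_equal(de$dice, 1)
  expect_true(de$empty)
  expect_error(dice_coefficient(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               class = "wsianno_format_error")
  # symmetry and monotone decrease under growing symmetric difference
  set.seed(44)
  base <- matrix(runif(400) < 0.4, 20, 20)
  prev <- 1
  other <- base
  for (flips in c(5, 20, 60, 120)) {
    other2 <- base
    idx <- sample(400, flips)
    other2[idx] <- !other2[idx]
    d1 <- dice_coefficient(base, other2)$dice
    expect_equal(d1, dice_coefficient(other2, base)$dice)
    expect_lte(d1, prev + 1e-12)
    prev <- d1
  }
})

test_that("clipped n-gram precision matches brute-force enumeration", {
  # candidate equals reference: precision 1 at all feasible orders
  toks <- c("nuclei", "rod-shaped", "tubular", "structure")
  for (n in 1:4) expect_equal(bleu_n(toks, toks, n)$precision, 1)
  # clipping: candidate "a a a" vs reference "a b"
  p <- bleu_n(c("a", "a", "a"), c("a", "b"), 1)
  expect_equal(p$precision, 1 / 3)
  # candidate shorter than n
  short <- bleu_n(c("a", "b"), c("a", "b"), 3)
  expect_equal(short$precision, 0)
  expect_true(short$short)
  expect_error(bleu_n(character(), c("a"), 1), class = "wsianno_empty_caption")
  # 100 random token strings vs the enumeration oracle
  set.seed(45)
  vocab <- letters[1:6]
  for (r in 1:100) {
    cand <- sample(vocab, sample(1:12, 1), replace = TRUE)
    refs <- lapply(seq_len(sample(1:3, 1)),
                   function(i) sample(vocab, sample(1:12, 1), replace = TRUE))
    n <- sample(1:4, 1)
    expect_equal(bleu_n(cand, refs, n)$precision, bleu_oracle(cand, refs, n))
  }
})

test_that("composite BLEU has the standard brevity penalty and zero-precision behavior", {
  ref <- c("irregular", "glandular", "duct", "arrangement", "cribriform",
           "structure", "necrosis", "prominent")
  # identity scores exactly 1 (no smoothing)
  expect_equal(bleu_composite(ref, ref)$bleu, 1)
  # prefix half: precisions 1, brevity penalty exp(1 - r/c)
  half <- ref[1:4]
  b <- bleu_composite(half, ref)
  expect_equal(b$brevity_penalty, exp(1 - 8 / 4))
  expect_equal(b$bleu, exp(1 - 2))
  # non-identical pair: BLEU < 1; any zero precision collapses to 0
  other <- c("nuclei", "remain", "polar", "tubular", "structure")
  expect_equal(bleu_composite(other, ref)$bleu, 0) # no shared 4-gram
  expect_gt(bleu_composite(other, ref, smoothing = "epsilon")$bleu, 0)
  # bounded in [0, 1] over random pairs; 1 only for identity
  set.seed(46)
  for (r in 1:30) {
    cand <- sample(letters[1:5], sample(4:10, 1), replace = TRUE)
    refr <- sample(letters[1:5], sample(4:10, 1), replace = TRUE)
    v <- bleu_composite(cand, refr)$bleu
    expect_gte(v, 0); expect_lte(v, 1)
    if (!identical(cand, refr)) expect_lt(v, 1)
  }
})

test_that("caption tokenization lowercases, splits and detokenizes terminology ids", {
  tree <- tiny_tree()
  expect_equal(tokenize_caption("Nuclei rod-shaped, tubular structure."),
               c("nuclei", "rod-shaped", "tubular", "structure"))
  expect_equal(tokenize_caption(c("r_ca1", "free:odd stroma"), tree),
               c("cribriform", "structure", "odd", "stroma"))
})

test_that("a document compared with itself agrees perfectly at every level", {
  doc <- tiny_doc()
  rep <- compare_annotations(doc, doc, patch_grid(32), tree = tiny_tree())
  expect_true(rep$wsi$agree)
  expect_equal(rep$patch_class$kappa, 1)
  expect_equal(rep$patch_subtype$kappa, 1)
  expect_true(all(rep$pixel_dice$dice == 1))
  expect_equal(rep$bleu1_mean, 1)
  expect_error(compare_annotations(doc, tiny_doc("other")),
               class = "wsianno_format_error")
  # tidy/glance views
  td <- generics::tidy(rep)
  expect_true(all(c("wsi_id", "level", "metric", "value") %in% names(td)))
  gl <- generics::glance(rep)
  expect_equal(gl$patch_kappa_class, 1)
  expect_equal(gl$mean_dice, 1)
})

test_that("label flips lower patch kappa as the flip model predicts; jitter only lowers Dice", {
  cfg <- synth_config(n_wsis = 4, image_size = 384, seed = 11,
                      class_mix = c(c_normal = 0, c_adenoma = 0.5, c_adenocarcinoma = 0.5))
  co <- generate_cohort(cfg)
  # pure boundary jitter: slide/patch agreement intact away from borders, Dice < 1
  doc <- co$docs[[1]]
  pj <- perturb_annotator(doc, co$tree, flip_rate = 0, jitter_px = 6, seed = 2)
  rep_j <- compare_annotations(doc, pj$doc, patch_grid(32))
  expect_true(all(rep_j$pixel_dice$dice < 1))
  expect_true(all(rep_j$pixel_dice$dice > 0.7))
  expect_true(rep_j$wsi$agree)

  # label flips with f = 0.3 (few regions per doc, so use a heavy rate and
  # pool all documents): observed patch agreement concentrates near 1 - f
  f <- 0.3
  pooled_a <- character(); pooled_b <- character()
  for (k in seq_along(co$docs)) {
    d <- co$docs[[k]]
    pb <- perturb_annotator(d, co$tree, flip_rate = f, jitter_px = 0, seed = 100 + k)
    g <- patch_grid(32)
    for (i in 0:(d$width / 32 - 1)) for (j in 0:(d$height / 32 - 1)) {
      ctr <- patch_center(g, i, j)
      la <- assign_patch_label(ctr, d$regions)$label_class
      lb <- assign_patch_label(ctr, pb$doc$regions)$label_class
      if (!is.na(la) || !is.na(lb)) {
        pooled_a <- c(pooled_a, ifelse(is.na(la), ".bg", la))
        pooled_b <- c(pooled_b, ifelse(is.na(lb), ".bg", lb))
      }
    }
  }
  p_o <- mean(pooled_a == pooled_b)
  n_regions <- sum(vapply(co$docs, function(d) sum(d$regions$layer == "decision"), numeric(1)))
  se <- sqrt(f * (1 - f) / n_regions) # flips act at region granularity
  expect_lt(abs(p_o - (1 - f)), 3 * se)
})

test_that("audit diff reports adds, removals and label changes", {
  doc <- tiny_doc()
  expect_equal(nrow(audit_diff(doc, doc)$added), 0)
  expect_equal(nrow(audit_diff(doc, doc)$removed), 0)
  expect_equal(nrow(audit_diff(doc, doc)$modified), 0)

  # delete one region
  doc_del <- tiny_doc()
  keep <- doc_del$regions$id != "r3"
  doc_del$regions <- doc_del$regions[keep, ]
  d <- audit_diff(doc, doc_del)
  expect_equal(d$removed$id, "r3")
  expect_equal(nrow(d$added), 0)

  # relabel one region
  doc_rel <- tiny_doc()
  doc_rel$regions$class_label[doc_rel$regions$id == "d2"] <- "c_adenocarcinoma"
  doc_rel$regions$subtype_label[doc_rel$regions$id == "d2"] <- "s_ca1"
  d2 <- audit_diff(doc, doc_rel)
  expect_equal(nrow(d2$modified), 1)
  expect_match(d2$modified$what, "label")
})

test_that("audit diff reconstructs a scripted edit log", {
  set.seed(47)
  for (rep in 1:5) {
    doc <- random_doc(paste0("w", rep), n_decision = 3, n_reason = 3)
    pb <- perturb_annotator(doc, tiny_tree(), flip_rate = 0.5, jitter_px = 0, seed = rep)
    d <- audit_diff(doc, pb$doc)
    # no geometry changed: every region matches, modifications = scripted flips
    expect_equal(nrow(d$added), 0)
    expect_equal(nrow(d$removed), 0)
    flipped <- unique(pb$edit_log$region_id[pb$edit_log$field == "class_label"])
    expect_setequal(d$modified$old_id, flipped)
  }
})

test_that("classification_report reproduces the published confusion-matrix metrics", {
  labels <- c("normal", "adenoma", "adenocarcinoma")
  coarse <- confusion_matrix(rbind(
    c(5317, 483, 2039),
    c(28, 1687, 16),
    c(624, 26, 5517)
  ), labels)
  rep_c <- classification_report(coarse)
  expect_equal(round(100 * rep_c$accuracy, 2), 79.56)
  expect_equal(round(100 * rep_c$per_class$recall, 2), c(67.83, 97.46, 89.46))

  fine <- confusion_matrix(rbind(
    c(6202, 297, 1340),
    c(69, 1622, 40),
    c(565, 8, 5594)
  ), labels)
  rep_f <- classification_report(fine)
  expect_equal(round(100 * rep_f$accuracy, 2), 85.26)
  expect_equal(round(100 * rep_f$per_class$recall, 2), c(79.12, 93.70, 90.71))

  # identity-like diagonal matrix: all metrics 100%
  diag_cm <- confusion_matrix(diag(c(5, 9, 2)), labels)
  rep_d <- classification_report(diag_cm)
  expect_equal(rep_d$accuracy, 1)
  expect_equal(rep_d$per_class$recall, rep(1, 3))
  expect_equal(rep_d$per_class$precision, rep(1, 3))

  # zero denominators are undefined, not zero
  m <- rbind(c(3, 0, 1), c(0, 0, 0), c(1, 0, 2))
  rep_z <- classification_report(confusion_matrix(m, labels))
  expect_true(is.na(rep_z$per_class$recall[2]))
  expect_true(is.na(rep_z$per_class$precision[2]))

  # tidy/glance and CSV round trip
  expect_equal(nrow(generics::tidy(rep_c)), 6)
  p <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(coarse, p)
  expect_equal(read_confusion_csv(p)$counts, coarse$counts)
})
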