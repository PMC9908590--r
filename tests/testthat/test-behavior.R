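mk_trace <- function(events, screen = c(1920, 1080)) {
  wsi_trace("w1", "annotA", events, screen_px = screen)
}

test_that("viewport intervals follow last-event-holds semantics", {
  # single fov event, trace ends 10 s later (voice event marks the end)
  tr <- mk_trace(tibble::tibble(
    t_ms = c(0, 10000), type = c("fov_center_change", "voice_start"),
    x = c(5000, NA), y = c(4000, NA), factor = NA_real_, pencil = NA_character_
  ))
  iv <- viewport_intervals(tr, slide_px = c(20000, 20000))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$dwell_s, 10)
  expect_equal(c(iv$cx, iv$cy), c(5000, 4000))

  # two fov events 4 s apart
  tr2 <- mk_trace(tibble::tibble(
    t_ms = c(0, 4000, 9000),
    type = c("fov_center_change", "fov_center_change", "voice_start"),
    x = c(1000, 3000, NA), y = c(1000, 3000, NA),
    factor = NA_real_, pencil = NA_character_
  ))
  iv2 <- viewport_intervals(tr2, c(20000, 20000))
  expect_equal(iv2$dwell_s, c(4, 5))

  # magnification doubling halves the rectangle side
  tr3 <- mk_trace(tibble::tibble(
    t_ms = c(0, 2000, 4000),
    type = c("fov_center_change", "magnification", "voice_start"),
    x = c(10000, NA, NA), y = c(10000, NA, NA),
    factor = c(NA, 2, NA), pencil = NA_character_
  ))
  iv3 <- viewport_intervals(tr3, c(20000, 20000))
  expect_equal(nrow(iv3), 2)
  expect_equal(iv3$x1[1] - iv3$x0[1], 1920)
  expect_equal(iv3$x1[2] - iv3$x0[2], 960)
  expect_equal(iv3$y1[2] - iv3$y0[2], 540)
  # both centered on the held fov center
  expect_equal((iv3$x0 + iv3$x1) / 2, c(10000, 10000))

  # idle truncation
  tr4 <- mk_trace(tibble::tibble(
    t_ms = c(0, 500000), type = c("fov_center_change", "voice_start"),
    x = c(100, NA), y = c(100, NA), factor = NA_real_, pencil = NA_character_
  ))
  expect_equal(viewport_intervals(tr4, c(1000, 1000))$dwell_s, 120)
  expect_equal(viewport_intervals(tr4, c(1000, 1000), idle_cap_s = 10)$dwell_s, 10)

  # no fov events at all
  tr5 <- mk_trace(tibble::tibble(
    t_ms = 0, type = "voice_start", x = NA_real_, y = NA_real_,
    factor = NA_real_, pencil = NA_character_
  ))
  expect_error(viewport_intervals(tr5, c(1000, 1000)), class = "wsianno_empty_trace")
})

test_that("heatmap deposits conserve cell-seconds", {
  # one rect covering exactly 2x2 cells held 6 s
  tr <- mk_trace(tibble::tibble(
    t_ms = c(0, 6000), type = c("fov_center_change", "voice_start"),
    x = c(256, NA), y = c(256, NA), factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  g <- attention_heatmap(tr, slide_px = c(1024, 1024), cell_px = 256)
  expect_equal(sum(g$cells > 0), 4)
  expect_equal(unique(as.numeric(g$cells[g$cells > 0])), 6)
  expect_equal(sum(g$cells), 24) # dwell x covered cells
  expect_equal(g$total_dwell_s, 6)

  # two overlapping rects: overlap cells carry both dwells (hand arithmetic)
  tr2 <- mk_trace(tibble::tibble(
    t_ms = c(0, 4000, 9000),
    type = c("fov_center_change", "fov_center_change", "voice_start"),
    x = c(256, 512, NA), y = c(256, 256, NA),
    factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  g2 <- attention_heatmap(tr2, c(1024, 1024), 256)
  # first rect cells (0:1, 0:1) get 4 s; second (1:2, 0:1) gets 5 s; overlap col 1
  expect_equal(g2$cells[1, 1], 4)
  expect_equal(g2$cells[1, 2], 9)
  expect_equal(g2$cells[1, 3], 5)
  expect_equal(sum(g2$cells), 4 * 4 + 5 * 4)
})

test_that("heat is additive under interval splitting and translates with centers", {
  # splitting one interval into two consecutive ones at the same center
  one <- mk_trace(tibble::tibble(
    t_ms = c(0, 8000), type = c("fov_center_change", "voice_start"),
    x = c(300, NA), y = c(300, NA), factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  two <- mk_trace(tibble::tibble(
    t_ms = c(0, 3000, 8000),
    type = c("fov_center_change", "fov_center_change", "voice_start"),
    x = c(300, 300, NA), y = c(300, 300, NA),
    factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  expect_equal(attention_heatmap(one, c(2048, 2048), 256)$cells,
               attention_heatmap(two, c(2048, 2048), 256)$cells)

  # shifting all centers by one cell shifts the heat by one cell
  base <- mk_trace(tibble::tibble(
    t_ms = c(0, 5000), type = c("fov_center_change", "voice_start"),
    x = c(640, NA), y = c(640, NA), factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  shifted <- mk_trace(tibble::tibble(
    t_ms = c(0, 5000), type = c("fov_center_change", "voice_start"),
    x = c(640 + 256, NA), y = c(640, NA), factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  ga <- attention_heatmap(base, c(4096, 4096), 256)$cells
  gb <- attention_heatmap(shifted, c(4096, 4096), 256)$cells
  expect_equal(ga[, 1:(ncol(ga) - 1)], gb[, 2:ncol(gb)])
})

test_that("dwell is attributed to the region containing the viewport center", {
  regions <- dplyr::bind_rows(
    anno_region("R", square_poly(100, 100, 200), "decision", "c_adenoma", "s_ad1"),
    anno_region("S", square_poly(600, 600, 100), "decision", "c_normal", "s_nm1")
  )
  # center always inside R
  tr <- mk_trace(tibble::tibble(
    t_ms = c(0, 3000, 7000),
    type = c("fov_center_change", "fov_center_change", "voice_start"),
    x = c(150, 250, NA), y = c(150, 250, NA),
    factor = NA_real_, pencil = NA_character_
  ))
  dw <- dwell_by_region(tr, regions, c(1000, 1000))
  expect_equal(dw$region_id, "R")
  expect_equal(dw$dwell_s, 7)

  # centers outside all regions: empty mapping
  tr2 <- mk_trace(tibble::tibble(
    t_ms = c(0, 5000), type = c("fov_center_change", "voice_start"),
    x = c(900, NA), y = c(50, NA), factor = NA_real_, pencil = NA_character_
  ))
  expect_equal(nrow(dwell_by_region(tr2, regions, c(1000, 1000))), 0)

  # random trace vs brute-force per-interval attribution
  set.seed(51)
  ev <- tibble::tibble(
    t_ms = cumsum(sample(500:3000, 30, replace = TRUE)),
    type = "fov_center_change",
    x = sample(0:999, 30, replace = TRUE), y = sample(0:999, 30, replace = TRUE),
    factor = NA_real_, pencil = NA_character_
  )
  tr3 <- mk_trace(ev)
  dw3 <- dwell_by_region(tr3, regions, c(1000, 1000))
  iv <- viewport_intervals(tr3, c(1000, 1000))
  brute <- c(R = 0, S = 0)
  for (k in seq_len(nrow(iv))) {
    for (rid in c("R", "S")) {
      poly <- regions$polygon[[which(regions$id == rid)]]
      if (point_in_polygon(iv$cx[k], iv$cy[k], poly)) {
        brute[rid] <- brute[rid] + iv$dwell_s[k]
        break
      }
    }
  }
  got <- setNames(rep(0, 2), c("R", "S"))
  got[dw3$region_id] <- dw3$dwell_s
  expect_equal(as.numeric(got), as.numeric(brute))
  expect_lte(sum(dw3$dwell_s), sum(iv$dwell_s))
})

test_that("generated traces dwell inside lesions as configured", {
  cfg <- synth_config(n_wsis = 1, image_size = 512, seed = 13,
                      class_mix = c(c_normal = 0, c_adenoma = 0, c_adenocarcinoma = 1))
  doc <- generate_cohort(cfg)$docs[[1]]
  lesions <- doc$regions[doc$regions$layer == "decision", ]

  # bias 1: every interval center inside a lesion
  tr1 <- generate_trace(doc, dwell_lesion_bias = 1, duration_s = 30, seed = 1)
  iv1 <- viewport_intervals(tr1, c(doc$width, doc$height))
  inside1 <- vapply(seq_len(nrow(iv1)), function(k) {
    any(vapply(lesions$polygon,
               function(p) point_in_polygon(iv1$cx[k], iv1$cy[k], p), logical(1)))
  }, logical(1))
  expect_true(all(inside1))

  # bias 0.8 over a long trace: measured dwell fraction within Monte-Carlo CI
  tr <- generate_trace(doc, dwell_lesion_bias = 0.8, duration_s = 240, seed = 2)
  iv <- viewport_intervals(tr, c(doc$width, doc$height))
  inside <- vapply(seq_len(nrow(iv)), function(k) {
    any(vapply(lesions$polygon,
               function(p) point_in_polygon(iv$cx[k], iv$cy[k], p), logical(1)))
  }, logical(1))
  frac <- sum(iv$dwell_s[inside]) / sum(iv$dwell_s)
  se <- sqrt(0.8 * 0.2 / nrow(iv))
  expect_lt(abs(frac - 0.8), 4 * se)

  # heat concentrates inside lesions (one-sided, seeded)
  g <- attention_heatmap(tr, c(doc$width, doc$height), cell_px = 64)
  cell_centers_x <- (col(g$cells) - 0.5) * 64
  cell_centers_y <- (row(g$cells) - 0.5) * 64
  in_lesion <- matrix(FALSE, nrow(g$cells), ncol(g$cells))
  for (p in lesions$polygon) {
    in_lesion <- in_lesion | matrix(
      point_in_polygon(as.numeric(cell_centers_x), as.numeric(cell_centers_y), p),
      nrow(g$cells), ncol(g$cells)
    )
  }
  expect_gt(mean(g$cells[in_lesion]), mean(g$cells[!in_lesion]))
})

test_that("heatmap rendering and CSV dumps are deterministic", {
  tr <- mk_trace(tibble::tibble(
    t_ms = c(0, 2000, 5000),
    type = c("fov_center_change", "fov_center_change", "voice_start"),
    x = c(300, 700, NA), y = c(300, 700, NA),
    factor = NA_real_, pencil = NA_character_
  ), screen = c(512, 512))
  g <- attention_heatmap(tr, c(1024, 1024), 256)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap_png(g, p1)
  render_heatmap_png(g, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))

  # all-zero grid renders uniform background
  g0 <- g; g0$cells[] <- 0
  render_heatmap_png(g0, p1)
  img <- png::readPNG(p1)
  expect_equal(length(unique(as.numeric(img))), 1)

  # CSV dump matches the grid cell-by-cell
  pc <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(g, pc)
  back <- readr::read_csv(pc, show_col_types = FALSE)
  expect_equal(nrow(back), length(g$cells))
  for (r in sample(nrow(back), 10)) {
    expect_equal(back$dwell_s[r], g$cells[back$cell_j[r] + 1, back$cell_i[r] + 1])
  }
  # ggplot view builds
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
})
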