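test_that("nuclear mask applies the 60%-of-maximum rule", {
  # stretched image with max 200: pixels >= 120 become mask
  px <- matrix(c(0, 50, 119, 120, 150, 200), 2, 3)
  m <- make_nuclear_mask(chan(px, role = "nuclear"), 0.6)
  expect_equal(as.vector(m), as.integer(px >= 120))

  # two Gaussian nuclei whose cores alone exceed the threshold
  img <- matrix(10, 64, 64)
  img <- fociscan:::render_granule(img, 16, 16, 4, 4, 190, FALSE)
  img <- fociscan:::render_granule(img, 48, 48, 4, 4, 190, FALSE)
  m2 <- make_nuclear_mask(chan(img, role = "nuclear"), 0.6)
  expect_equal(max(fociscan:::label8_cpp(m2)), 2L)

  expect_warning(make_nuclear_mask(chan(matrix(200, 8, 8), role = "nuclear")),
                 "degenerate")
  expect_warning(m0 <- make_nuclear_mask(chan(matrix(c(200, rep(0, 63)), 8, 8),
                                              role = "nuclear"), 0.9),
                 NA)
  dim_ok <- dim(m0)
  expect_equal(dim_ok, c(8L, 8L))
})

test_that("nuclear mask fills interior holes (nucleolar dark spots)", {
  img <- matrix(0, 21, 21)
  img[6:16, 6:16] <- 200
  img[10:12, 10:12] <- 0  # dark nucleolus
  m <- make_nuclear_mask(chan(img, role = "nuclear"), 0.6)
  expect_equal(m[11, 11], 1L)
  expect_equal(sum(m), 11L * 11L)
})

test_that("elevation surface has nuclei at 0 and empty background on top", {
  foci <- chan(matrix(c(0, 100, 255), 1, 3), max_intensity = 255)
  nm <- matrix(c(1L, 0L, 0L), 1, 3)
  elev <- build_elevation(foci, nm, gain = 2)
  expect_equal(elev[1, 1], 0)          # nuclear pixel forced to 0
  expect_equal(elev[1, 2], 255 - 200)  # gain doubles intensity first
  expect_equal(elev[1, 3], 0)          # saturated foci pixel
  elev2 <- build_elevation(foci, matrix(0L, 1, 3), gain = 2)
  expect_equal(elev2[1, 1], 255)       # background reaches the cap
})

test_that("marker-controlled watershed honors the marker contract", {
  # single nucleus: one basin covering the whole field (no ridges possible)
  nm <- matrix(0L, 32, 32); nm[15:18, 15:18] <- 1L
  elev <- matrix(runif(32 * 32, 0, 10), 32, 32)
  clm <- segment_cells(elev, nm, 0.2)
  expect_equal(nrow(clm$nuclei), 1L)
  expect_true(all(clm$labels == 1L))

  # two nuclei separated by a bright ridge: each keeps its own half
  nm2 <- matrix(0L, 64, 64)
  nm2[30:34, 10:14] <- 1L
  nm2[30:34, 50:54] <- 1L
  elev2 <- matrix(0, 64, 64)
  elev2[, 31:33] <- 100  # elevation wall between the two
  clm2 <- segment_cells(elev2, nm2, 0.2)
  expect_equal(nrow(clm2$nuclei), 2L)
  expect_true(all(clm2$labels[, 1:30] %in% c(0L, clm2$labels[32, 12])))
  expect_true(all(clm2$labels[, 34:64] %in% c(0L, clm2$labels[32, 52])))
  expect_true(all(clm2$labels[nm2 == 1L] > 0L))

  # k synthetic nuclei give exactly k labels, each marker intact in a basin
  f <- generate_field(quick_spec(42))
  nuc <- contrast_stretch(clip_intensity(f$images$nuclear, quiet = TRUE))
  nm3 <- make_nuclear_mask(nuc)
  fo <- wiener_denoise(clip_intensity(f$images$foci, quiet = TRUE))
  clm3 <- segment_cells(build_elevation(fo, nm3), nm3, 0.2)
  expect_equal(nrow(clm3$nuclei), nrow(f$truth$cells))
  # partition property: labels plus ridges tile the field
  expect_true(all(clm3$labels >= 0L))
  expect_true(all(clm3$labels <= nrow(clm3$nuclei)))
})

test_that("small-cell filter removes cells below the area threshold", {
  nm <- matrix(0L, 40, 40)
  nm[8:10, 8:10] <- 1L    # nucleus of a small cell
  nm[28:32, 28:32] <- 1L  # nucleus of a large cell
  elev <- matrix(0, 40, 40)
  elev[, 19:21] <- 100
  clm <- segment_cells(elev, nm, 1)  # 1 um/px for easy areas
  fg <- matrix(0L, 40, 40)
  fg[4:14, 4:14] <- 1L    # 121 px -> 121 um2... shrink to force removal
  fg[4:14, 4:14] <- 0L
  fg[6:10, 6:10] <- 1L    # 25 um2 < 30 for cell 1
  fg[23:37, 23:37] <- 1L  # 225 um2 for cell 2
  filt <- filter_small_cells(clm, 30, fg)
  expect_equal(nrow(filt$nuclei), 1L)
  keep_id <- filt$nuclei$cell_id
  expect_true(all(filt$labels %in% c(0L, keep_id)))

  # threshold 0 is the identity
  same <- filter_small_cells(clm, 0, fg)
  expect_equal(nrow(same$nuclei), 2L)

  # brute-force area filter agreement on a synthetic field
  f <- generate_field(quick_spec(77))
  nuc <- contrast_stretch(clip_intensity(f$images$nuclear, quiet = TRUE))
  nm2 <- make_nuclear_mask(nuc)
  fo <- wiener_denoise(clip_intensity(f$images$foci, quiet = TRUE))
  clm2 <- segment_cells(build_elevation(fo, nm2), nm2, 0.2)
  fg2 <- cell_foreground(fo)
  thr <- 120  # um2, between typical small and large cells
  filt2 <- filter_small_cells(clm2, thr, fg2)
  areas <- vapply(clm2$nuclei$cell_id, function(k)
    sum(clm2$labels == k & fg2 == 1L) * 0.2^2, 0)
  expect_setequal(filt2$nuclei$cell_id, clm2$nuclei$cell_id[areas >= thr])
})

test_that("cell foreground approximates the true cell footprint", {
  expect_equal(cell_foreground(chan(matrix(runif(100), 10, 10)), 0),
               matrix(1L, 10, 10))

  f <- generate_field(quick_spec(9))
  fo <- wiener_denoise(clip_intensity(f$images$foci, quiet = TRUE))
  fg <- cell_foreground(fo)
  truth_fg <- (f$truth$cell_labels > 0L) * 1L
  jac <- sum(fg == 1L & truth_fg == 1L) / sum(fg == 1L | truth_fg == 1L)
  expect_gt(jac, 0.9)
  # pure background pixels excluded
  expect_lt(mean(fg[f$truth$cell_labels == 0L]), 0.05)
})

test_that("planted granules land in the basin of their own cell", {
  hits <- 0; tot <- 0
  for (s in 1:5) {
    f <- generate_field(quick_spec(500 + s))
    nuc <- contrast_stretch(clip_intensity(f$images$nuclear, quiet = TRUE))
    nm <- make_nuclear_mask(nuc)
    fo <- wiener_denoise(clip_intensity(f$images$foci, quiet = TRUE))
    clm <- segment_cells(build_elevation(fo, nm), nm, 0.2)
    tc <- f$truth$cells
    basin_of <- clm$labels[cbind(round(tc$row), round(tc$col))]
    g <- f$truth$granules
    if (!nrow(g)) next
    tot <- tot + nrow(g)
    hits <- hits + sum(clm$labels[cbind(g$row, g$col)] == basin_of[g$cell_id])
  }
  expect_gte(hits / tot, 0.95)
})
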