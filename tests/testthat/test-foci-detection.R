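test_that("prototype extraction crops the expected patch", {
  set.seed(2)
  img <- chan(matrix(runif(200 * 200, 0, 255), 200, 200))
  p <- extract_prototype(img, c(100, 100), granule_box = 5L, margin = 2L)
  expect_equal(dim(p$patch), c(9L, 9L))
  expect_equal(p$patch[5, 5], img$pixels[100, 100])

  p0 <- extract_prototype(img, c(50, 60), granule_box = 7L, margin = 0L)
  expect_equal(dim(p0$patch), c(7L, 7L))

  expect_error(extract_prototype(img, c(2, 2), 5L, 2L), "fit")
  flat <- chan(matrix(7, 50, 50))
  expect_error(extract_prototype(flat, c(25, 25), 5L, 2L), "variance")
})

test_that("self-correlation at the extraction centre is exactly 1", {
  set.seed(8)
  img <- chan(matrix(runif(80 * 80, 0, 255), 80, 80))
  p <- extract_prototype(img, c(40, 41), granule_box = 5L, margin = 3L)
  cm <- normxcorr(img, p)
  expect_equal(cm$values[40, 41], 1, tolerance = 1e-12)
})

test_that("prototype rotation forms the cyclic group of order 4", {
  set.seed(4)
  p <- prototype(matrix(runif(49), 7, 7), "I", 0.85)
  r1 <- rotate_prototype(p, 1)
  r4 <- rotate_prototype(rotate_prototype(r1, 1), 2)
  expect_equal(r4$patch, p$patch)
  expect_equal(r1$similarity_threshold, p$similarity_threshold)
  expect_equal(r1$rotation_deg, 90L)

  # rotationally symmetric patch: rotation changes nothing
  sym <- matrix(0, 9, 9); sym <- fociscan:::render_granule(sym, 5, 5, 1.5, 1.5, 100, FALSE)
  ps <- prototype(sym, "S", 0.8)
  expect_equal(rotate_prototype(ps, 1)$patch, ps$patch)
})

test_that("normxcorr matches the sliding-window Pearson oracle", {
  set.seed(19)
  for (rep in 1:4) {
    img <- matrix(runif(24 * 24, 0, 255), 24, 24)
    patch <- matrix(runif(25, 0, 255), 5, 5)
    got <- normxcorr(chan(img), prototype(patch, "T", 0.5))$values
    want <- ncc_oracle(img, patch)
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
    expect_identical(is.na(got), is.na(want))
  }
})

test_that("normxcorr is invariant to positive affine intensity maps", {
  set.seed(23)
  img <- matrix(runif(40 * 40, 10, 100), 40, 40)
  patch <- img[15:21, 10:16]
  p <- prototype(patch, "A", 0.5)
  a <- normxcorr(chan(img), p)$values
  b <- normxcorr(chan(1.8 * img + 12, bit_depth = 16L), p)$values
  expect_equal(a, b, tolerance = 1e-9)
  # window identical to an affine image of the patch scores 1
  expect_equal(b[18, 13], 1, tolerance = 1e-12)
})

test_that("seed thresholding is strict and elementwise", {
  vals <- matrix(NA_real_, 5, 5)
  vals[3, 3] <- 0.9
  cm <- structure(list(values = vals, prototype_id = "I"),
                  class = "correlation_map")
  s <- threshold_seeds(cm, 0.85)
  expect_equal(sum(s$pixels), 1L)
  expect_true(s$pixels[3, 3])
  expect_equal(sum(threshold_seeds(cm, 0.9)$pixels), 0L)  # strict inequality

  set.seed(31)
  rv <- matrix(runif(100, -1, 1), 10, 10)
  cm2 <- structure(list(values = rv, prototype_id = "II"),
                   class = "correlation_map")
  expect_equal(threshold_seeds(cm2, 0.4)$pixels, rv > 0.4)
})

test_that("bank detection is the union over prototypes and passes", {
  f <- generate_field(quick_spec(61))
  img <- clip_intensity(f$images$foci, quiet = TRUE)
  bank <- default_prototype_bank()
  one <- prototype_bank(bank$prototypes[2])

  s_one <- detect_seeds(img, one, use_sharpened_pass = FALSE)
  direct <- threshold_seeds(normxcorr(img, bank$prototypes[[2]]),
                            bank$prototypes[[2]]$similarity_threshold)
  expect_equal(s_one$pixels, direct$pixels)

  s_all <- detect_seeds(img, bank, use_sharpened_pass = FALSE)
  per <- lapply(bank$prototypes, function(p)
    threshold_seeds(normxcorr(img, p), p$similarity_threshold)$pixels)
  expect_equal(s_all$pixels, Reduce(`|`, per))

  # detection output does not depend on prototype order
  shuf <- prototype_bank(bank$prototypes[c(5, 2, 8, 1, 3, 7, 4, 6)])
  s_shuf <- detect_seeds(img, shuf, use_sharpened_pass = FALSE)
  expect_equal(s_shuf$pixels, s_all$pixels)
})

test_that("the sharpened pass only adds seeds, via the filtered image", {
  f <- generate_field(quick_spec(73))
  img <- clip_intensity(f$images$foci, quiet = TRUE)
  bank <- default_prototype_bank()
  raw <- detect_seeds(img, bank, use_sharpened_pass = FALSE)
  both <- detect_seeds(img, bank, use_sharpened_pass = TRUE)
  # union semantics: the second pass can never remove a raw seed
  expect_true(all(both$pixels[raw$pixels]))
  # and the added seeds are exactly the bank's crossings on the unsharp image
  sharp_only <- detect_seeds(unsharp_filter(img, 0.2), bank,
                             use_sharpened_pass = FALSE)
  expect_equal(both$pixels, raw$pixels | sharp_only$pixels)
})

test_that("seed masking removes nuclear and extracellular seeds", {
  set.seed(9)
  pix <- matrix(runif(400) > 0.6, 20, 20)
  s <- structure(list(pixels = pix, by_prototype = list(I = pix)),
                 class = "seed_map")
  nm <- matrix(rbinom(400, 1, 0.3), 20, 20)
  fg <- matrix(rbinom(400, 1, 0.7), 20, 20)
  out <- mask_seeds(s, nm, fg)
  expect_equal(out$pixels, pix & nm != 1L & fg == 1L)
  expect_equal(out$by_prototype$I, out$pixels)
  # nuclear seed removed, cytoplasmic kept
  s2 <- structure(list(pixels = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                       by_prototype = list()), class = "seed_map")
  nm2 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  out2 <- mask_seeds(s2, nm2, matrix(1L, 2, 2))
  expect_false(out2$pixels[1, 1])
  expect_true(out2$pixels[2, 1])
})

test_that("seed merging follows 3x3 dilation geometry", {
  mk <- function(pts, dim = c(24, 24)) {
    px <- matrix(FALSE, dim[1], dim[2])
    px[pts] <- TRUE
    structure(list(pixels = px, by_prototype = list(I = px)),
              class = "seed_map")
  }
  # single isolated seed dilates to exactly 9 pixels
  one <- merge_seeds(mk(cbind(12, 12)), 0.2)
  expect_length(one, 1L)
  expect_equal(one[[1]]$pixel_count, 9L)
  expect_equal(one[[1]]$point, c(12, 12))
  expect_equal(one[[1]]$area_um2, 9 * 0.04)

  # Chebyshev distance 3 merges, 5 stays separate
  expect_length(merge_seeds(mk(rbind(c(10, 10), c(13, 10))), 0.2), 1L)
  expect_length(merge_seeds(mk(rbind(c(10, 10), c(13, 13))), 0.2), 1L)
  expect_length(merge_seeds(mk(rbind(c(10, 10), c(15, 10))), 0.2), 2L)

  # provenance: both prototypes hitting one object are recorded
  px <- matrix(FALSE, 20, 20); px[8, 8] <- TRUE
  px2 <- matrix(FALSE, 20, 20); px2[9, 9] <- TRUE
  s <- structure(list(pixels = px | px2,
                      by_prototype = list(I = px, II = px2)),
                 class = "seed_map")
  obj <- merge_seeds(s, 0.2)
  expect_length(obj, 1L)
  expect_setequal(obj[[1]]$prototype_hits, c("I", "II"))
})

test_that("every seed belongs to exactly one merged object", {
  set.seed(12)
  px <- matrix(runif(900) > 0.92, 30, 30)
  s <- structure(list(pixels = px, by_prototype = list(I = px)),
                 class = "seed_map")
  objs <- merge_seeds(s, 0.2)
  expect_lte(length(objs), sum(px))
  all_idx <- unlist(lapply(objs, `[[`, "pixel_idx"))
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_true(all(which(px) %in% all_idx))
  for (o in objs) {
    pt_idx <- (o$point[2] - 1L) * 30L + o$point[1]
    expect_true(pt_idx %in% o$pixel_idx)
  }
})

test_that("prototype redundancy matrix counts joint hits", {
  bank <- prototype_bank(list(
    prototype(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3), "I", 0.8),
    prototype(matrix(c(5, 1, 2, 8, 3, 9, 4, 7, 6), 3, 3), "II", 0.8)))
  mkobj <- function(hits) mk_focus(1, 1, c(10, 10)) |>
    (\(f) { f$prototype_hits <- hits; f })()
  # every object hit by exactly one prototype: off-diagonal zero
  objs <- list(mkobj("I"), mkobj("I"), mkobj("II"), mkobj("II"))
  m <- prototype_redundancy(objs, bank)
  expect_equal(m["I", "I"], 50)
  expect_equal(m["II", "II"], 50)
  expect_equal(m["II", "I"], 0)
  # all objects hit by all prototypes
  allhit <- list(mkobj(c("I", "II")), mkobj(c("I", "II")))
  m2 <- prototype_redundancy(allhit, bank)
  expect_true(all(m2[lower.tri(m2, diag = TRUE)] == 100))
  # brute-force agreement on random hit sets
  set.seed(6)
  rnd <- lapply(1:30, function(i)
    mkobj(sample(c("I", "II"), sample(1:2, 1))))
  m3 <- prototype_redundancy(rnd, bank)
  both <- sum(vapply(rnd, function(f)
    all(c("I", "II") %in% f$prototype_hits), logical(1)))
  expect_equal(m3["II", "I"], 100 * both / 30)
})

test_that("size reliability uses the larger bounding-box side", {
  f3 <- mk_focus(5, 5, c(20, 20))
  f3$bbox_side_px <- 3L
  expect_false(size_reliability(f3, 6L))
  f10 <- mk_focus(5, 5, c(20, 20))
  f10$bbox_side_px <- 10L
  expect_true(size_reliability(f10, 6L))
  f7 <- mk_focus(5, 5, c(20, 20))
  f7$bbox_side_px <- 6L
  expect_false(size_reliability(f7, 6L))  # strict: width must exceed 6
})

test_that("a prototype bank survives a directory round trip", {
  bank <- default_prototype_bank()
  dir <- withr::local_tempdir()
  write_prototype_bank(bank, dir)
  back <- read_prototype_bank(dir)
  expect_equal(length(back), length(bank))
  for (i in seq_along(bank$prototypes)) {
    expect_equal(back$prototypes[[i]]$id, bank$prototypes[[i]]$id)
    expect_equal(back$prototypes[[i]]$similarity_threshold,
                 bank$prototypes[[i]]$similarity_threshold)
    # patches are stored as 8-bit TIFF: integer-rounded but shape-identical
    expect_equal(back$prototypes[[i]]$patch,
                 round(bank$prototypes[[i]]$patch), ignore_attr = TRUE)
  }
})

test_that("minimum-area focus filter drops small objects", {
  a <- mk_focus(2, 2, c(30, 30), pix = 1:9)      # 9 px * 0.04 = 0.36 um2
  b <- mk_focus(10, 10, c(30, 30), pix = 1:3)    # 0.12 um2
  out <- filter_small_foci(list(a, b), 0.2)
  expect_length(out, 1L)
  expect_equal(out[[1]]$pixel_count, 9L)
  expect_length(filter_small_foci(list(a, b), 0), 2L)
})
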