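test_that("foci are assigned by the label under their representative point", {
  labels <- matrix(0L, 20, 20)
  labels[1:20, 1:9] <- 1L
  labels[1:20, 11:20] <- 3L   # column 10 is a ridge
  clm <- structure(list(labels = labels,
                        nuclei = data.frame(cell_id = c(1L, 3L),
                                            basin_area_um2 = c(1, 1)),
                        pixel_size_um = 0.2),
                   class = "cell_label_map")
  foci <- list(mk_focus(5, 5, c(20, 20)), mk_focus(7, 15, c(20, 20)),
               mk_focus(4, 10, c(20, 20)))
  out <- assign_foci_to_cells(foci, clm)
  expect_equal(vapply(out, `[[`, 0L, "cell_id"), c(1L, 3L, 0L))

  recs <- cell_records(clm, out)
  expect_equal(recs$n_foci, c(1L, 1L))
  expect_equal(attr(recs, "n_unassigned"), 1L)
})

test_that("per-cell counts on synthetic fields match planted truth", {
  f <- generate_field(quick_spec(303))
  out <- run_pipeline(list(f$images))
  tc <- f$truth$cells
  # map basin label at each true nucleus centre to the truth cell id
  clm <- out$label_maps[[1]]
  basin_of <- clm$labels[cbind(round(tc$row), round(tc$col))]
  got <- out$cells
  for (i in seq_len(nrow(tc))) {
    row <- got[got$cell_id == basin_of[i], ]
    expect_equal(row$n_foci, tc$n_granules_planted[i])
  }
  # conservation: assigned + unassigned = total foci
  expect_equal(sum(got$n_foci) + attr(out$cells, "n_unassigned")[1],
               nrow(out$foci))
})

test_that("field summary applies the two-or-more positivity rule", {
  # 20 cells, 11 positive carrying 40 foci in total
  n_foci <- c(rep(0L, 6), rep(1L, 3), 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L)
  stopifnot(length(n_foci) == 20L, sum(n_foci >= 2) == 11L,
            sum(n_foci[n_foci >= 2]) == 40L)
  cells <- data.frame(cell_id = 1:20, n_foci = n_foci,
                      positive = n_foci >= 2, area_um2 = 50)
  s <- summarize_field(cells, 2L)
  expect_equal(s$n_cells, 20L)
  expect_equal(s$n_positive_cells, 11L)
  expect_equal(s$pct_positive, 55)
  expect_equal(s$mean_foci_per_positive_cell, 40 / 11, tolerance = 1e-12)

  # no foci anywhere
  empty <- data.frame(cell_id = 1:5, n_foci = 0L, positive = FALSE,
                      area_um2 = 50)
  s0 <- summarize_field(empty, 2L)
  expect_equal(s0$pct_positive, 0)
  expect_true(is.na(s0$mean_foci_per_positive_cell))

  # random records equal a brute-force tally
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    cnt <- rpois(n, 1.5)
    cells <- data.frame(cell_id = seq_len(n), n_foci = cnt,
                        positive = cnt >= 2, area_um2 = 50)
    s <- summarize_field(cells, 2L)
    expect_equal(s$n_positive_cells, sum(cnt >= 2))
    expect_equal(s$pct_positive, 100 * sum(cnt >= 2) / n)
    if (any(cnt >= 2))
      expect_equal(s$mean_foci_per_positive_cell,
                   mean(rep(cnt[cnt >= 2], 1)) * sum(cnt >= 2) / sum(cnt >= 2))
  }

  # positivity invariant under cell relabeling and row permutation
  cells <- data.frame(cell_id = 1:10, n_foci = c(0, 3, 2, 0, 1, 5, 0, 2, 0, 4),
                      positive = NA, area_um2 = 50)
  perm <- cells[sample(1:10), ]
  perm$cell_id <- sample(100:109)
  expect_equal(summarize_field(perm, 2L)$pct_positive,
               summarize_field(cells, 2L)$pct_positive)
})

test_that("nearest distances follow the distance transform of the foci mask", {
  dimg <- c(50, 50)
  # single focus pixel at (10,10); target at (13,14): 3-4-5 triangle
  focus <- mk_focus(10, 10, dimg)
  target <- mk_focus(13, 14, dimg)
  r <- nearest_object_distances(list(target), list(focus), radius_um = 0.5,
                                dim = dimg, pixel_size_um = 1)
  expect_equal(r$distances_um, 5)
  expect_equal(r$fraction_within, 0)

  # target inside a focus has distance 0
  inside <- nearest_object_distances(list(focus), list(focus), 0.5, dimg, 1)
  expect_equal(inside$distances_um, 0)
  expect_equal(inside$fraction_within, 1)

  # empty foci list: infinite distances, fraction 0
  none <- nearest_object_distances(list(target), list(), 0.5, dimg, 1)
  expect_equal(none$distances_um, Inf)
  expect_equal(none$fraction_within, 0)
})

test_that("distance results equal the brute-force all-pairs oracle", {
  set.seed(27)
  for (rep in 1:25) {
    dimg <- c(40, 40)
    nf <- sample(1:6, 1); nt <- sample(1:6, 1)
    foci <- lapply(seq_len(nf), function(i) {
      r <- sample(3:38, 1); cc <- sample(3:38, 1)
      pix <- as.integer((cc - 1) * 40 + r + c(0, 1, 40))  # small 3-px object
      mk_focus(r, cc, dimg, pix = pix, id = i)
    })
    targets <- lapply(seq_len(nt), function(i)
      mk_focus(sample(1:40, 1), sample(1:40, 1), dimg, id = i))
    got <- nearest_object_distances(targets, foci, radius_um = 0.5,
                                    dim = dimg, pixel_size_um = 0.2)
    fp <- do.call(rbind, lapply(foci, function(f) {
      idx <- f$pixel_idx
      cbind((idx - 1) %% 40 + 1, (idx - 1) %/% 40 + 1)
    }))
    tp <- do.call(rbind, lapply(targets, function(t) rbind(t$point)))
    want <- nearest_oracle(tp, fp, 0.2)
    expect_equal(got$distances_um, want, tolerance = 1e-9)
    expect_equal(got$fraction_within, mean(want < 0.5))
  }
})

test_that("fraction within radius is monotone in the radius", {
  set.seed(33)
  dimg <- c(60, 60)
  foci <- lapply(1:8, function(i)
    mk_focus(sample(5:55, 1), sample(5:55, 1), dimg, id = i))
  targets <- lapply(1:15, function(i)
    mk_focus(sample(1:60, 1), sample(1:60, 1), dimg, id = i))
  fr <- vapply(c(0.3, 0.5, 1, 2, 4), function(r)
    nearest_object_distances(targets, foci, r, dimg, 0.2)$fraction_within, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("size change report compares group means against a reference", {
  g1 <- list(mk_focus(2, 2, c(10, 10), pix = 1:10),
             mk_focus(5, 5, c(10, 10), pix = 11:30))
  same <- size_change_report(list(a = g1, b = g1))
  expect_equal(same$ratio_vs_reference, c(1, 1))

  one_a <- list(mk_focus(2, 2, c(10, 10), pix = 1:10))
  one_b <- list(mk_focus(2, 2, c(10, 10), pix = 1:35))
  r <- size_change_report(list(ref = one_a, big = one_b))
  expect_equal(r$ratio_vs_reference[2], 3.5)

  # unreliable objects are excluded by default
  unrel <- mk_focus(8, 8, c(10, 10), pix = 1:100, reliable = FALSE)
  r2 <- size_change_report(list(ref = one_a, big = c(one_b, list(unrel))))
  expect_equal(r2$ratio_vs_reference[2], 3.5)
  expect_warning(size_change_report(list(ref = one_a, empty = list(unrel))),
                 "no usable objects")
})
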