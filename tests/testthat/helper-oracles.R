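# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own computational paths.

chan <- function(m, bit_depth = 8L, ps = 0.2, role = "foci", ...) {
  channel_image(m, bit_depth = bit_depth, pixel_size_um = ps, role = role, ...)
}

# sliding-window Pearson NCC, plain loops + stats::cor
ncc_oracle <- function(img, patch) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- nrow(patch); pc <- ncol(patch)
  hr <- pr %/% 2; hc <- pc %/% 2
  out <- matrix(NA_real_, nr, nc)
  pv <- as.vector(patch)
  for (i in (hr + 1):(nr - hr)) {
    for (j in (hc + 1):(nc - hc)) {
      win <- img[(i - hr):(i + hr), (j - hc):(j + hc)]
      wv <- as.vector(win)
      if (stats::var(wv) == 0) out[i, j] <- 0
      else out[i, j] <- stats::cor(wv, pv)
    }
  }
  out
}

# direct local Wiener filter with replicated borders, plain loops
wiener_oracle <- function(x, window = 3L) {
  h <- window %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[pmin(pmax(seq_len(nr + 2 * h) - h, 1), nr),
          pmin(pmax(seq_len(nc + 2 * h) - h, 1), nc)]
  mu <- s2 <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- xp[i:(i + 2 * h), j:(j + 2 * h)]
      mu[i, j] <- mean(win)
      s2[i, j] <- mean(win^2) - mean(win)^2
    }
  }
  nu <- mean(s2)
  out <- mu + pmax(s2 - nu, 0) / pmax(s2, nu) * (x - mu)
  out[s2 == 0 & nu == 0] <- mu[s2 == 0 & nu == 0]
  out
}

# direct 2-D correlation of a 3x3 kernel with replicated borders
conv3_oracle <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[pmin(pmax(seq_len(nr + 2) - 1, 1), nr),
          pmin(pmax(seq_len(nc + 2) - 1, 1), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- sum(xp[i:(i + 2), j:(j + 2)] * k)
  out
}

# brute-force nearest distance from points to any pixel of any focus object
nearest_oracle <- function(points, foci_px, ps) {
  vapply(seq_len(nrow(points)), function(i) {
    if (!nrow(foci_px)) return(Inf)
    min(sqrt((foci_px[, 1] - points[i, 1])^2 +
               (foci_px[, 2] - points[i, 2])^2)) * ps
  }, 0)
}

# exhaustive optimal one-to-one matching size (n <= 8 detections)
optimal_match_oracle <- function(dmat, radius) {
  nd <- nrow(dmat); ng <- ncol(dmat)
  best <- 0
  assign_next <- function(d, used_g, count) {
    if (count + (nd - d + 1) <= best) return()
    if (d > nd) { best <<- max(best, count); return() }
    assign_next(d + 1, used_g, count)
    for (g in seq_len(ng)) {
      if (!used_g[g] && dmat[d, g] <= radius) {
        used_g[g] <- TRUE
        assign_next(d + 1, used_g, count + 1)
        used_g[g] <- FALSE
      }
    }
  }
  assign_next(1, logical(ng), 0)
  best
}

# minimal focus-like object for quantification tests
mk_focus <- function(row, col, dim, pix = NULL, reliable = TRUE, id = 1L) {
  if (is.null(pix)) pix <- (col - 1L) * dim[1] + row
  structure(list(focus_id = id, point = c(row, col), pixel_idx = pix,
                 pixel_count = length(pix),
                 area_um2 = length(pix) * 0.04,
                 bbox_side_px = 3L, size_reliable = reliable,
                 cell_id = 0L, prototype_hits = character()),
            class = "focus")
}

# small fast synthetic spec for property tests
quick_spec <- function(seed, ...) {
  synthetic_spec(side = 256L, n_cells = 5L, cell_radius_um = c(5, 7),
                 seed = seed, ...)
}
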