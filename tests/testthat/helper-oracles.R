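# Independent oracles used across the suite. Deliberately brute-force and
# separate from the package implementation paths they check.

# Flood-fill connected-component labeling (BFS, 8- or 4-connectivity) on a
# logical mask. Labels numbered in column-major order of first discovery,
# matching the package's renumbering convention.
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8L) {
    di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L)
    dj <- c(0L, 0L, -1L, 1L)
  }
  stack_i <- integer(nr * nc); stack_j <- integer(nr * nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      top <- 1L; stack_i[1L] <- i; stack_j[1L] <- j
      lab[i, j] <- nxt
      while (top > 0L) {
        ci <- stack_i[top]; cj <- stack_j[top]; top <- top - 1L
        for (k in seq_along(di)) {
          ii <- ci + di[k]; jj <- cj + dj[k]
          if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            top <- top + 1L
            stack_i[top] <- ii; stack_j[top] <- jj
          }
        }
      }
    }
  }
  lab
}

# Brute-force one-way ANOVA from explicit sums of squares.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)
  f <- (ssb / df_b) / (ssw / df_w)
  list(f_stat = f, df_between = df_b, df_within = df_w,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# Direct (non-separable) convolution of an image with an explicitly
# constructed 2D negated-LoG kernel, edge-replicated at the border.
# O(n^2 k^2); small inputs only.
oracle_neg_log_response <- function(m, sigma_px) {
  r <- ceiling(4 * sigma_px)
  t <- (-r):r
  g1 <- dnorm(t, 0, sigma_px); g1 <- g1 / sum(g1)
  d2 <- ((t^2 - sigma_px^2) / sigma_px^4) * dnorm(t, 0, sigma_px)
  d2 <- d2 - mean(d2)
  k2 <- outer(d2, g1) + outer(g1, d2)   # Gyy + Gxx, rows = y
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in t) {
        ii <- min(max(i + a, 1L), nr)
        for (b in t) {
          jj <- min(max(j + b, 1L), nc)
          acc <- acc + m[ii, jj] * k2[a + r + 1L, b + r + 1L]
        }
      }
      out[i, j] <- -acc
    }
  }
  out[out < 0] <- 0
  out
}

# Photon mass of an isotropic Gaussian emitter integrated over one pixel,
# by midpoint quadrature of the 2D density (independent of the pnorm-based
# renderer).
oracle_pixel_mass <- function(x0, y0, sigma, px, row, col, n_quad = 801L) {
  xs <- ((col - 1L) * px) + (seq_len(n_quad) - 0.5) / n_quad * px
  ys <- ((row - 1L) * px) + (seq_len(n_quad) - 0.5) / n_quad * px
  fx <- dnorm(xs, x0, sigma)
  fy <- dnorm(ys, y0, sigma)
  sum(outer(fy, fx)) * (px / n_quad)^2
}

# Hand-built scene_truth for deterministic renderer tests.
manual_truth <- function(emitters, params,
                         width_nm = NULL, height_nm = NULL) {
  size <- cristaequant:::scene_image_size_nm(params)
  if (!is.null(width_nm)) size[["width_nm"]] <- width_nm
  if (!is.null(height_nm)) size[["height_nm"]] <- height_nm
  structure(list(emitters = emitters,
                 centers = data.frame(x_nm = numeric(0),
                                      y_offset_nm = numeric(0),
                                      cluster_id = integer(0)),
                 params = params,
                 margin_nm = cristaequant:::scene_margin_nm(params),
                 image_nm = size),
            class = "scene_truth")
}

# Segmentation object with prescribed per-segment pixel counts, for
# forced-arithmetic tests of the clustered fraction. Segments are laid out
# as isolated horizontal runs.
manual_segmentation <- function(px_counts, pixel_size_nm) {
  n <- length(px_counts)
  nr <- max(8L, 2L * n + 1L)
  nc <- max(8L, max(px_counts) + 2L)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n)) lab[2L * i, seq_len(px_counts[i]) + 1L] <- i
  structure(list(label_map = lab,
                 segment_areas_um2 = setNames(
                   px_counts * (pixel_size_nm / 1000)^2,
                   as.character(seq_len(n))),
                 pixel_size_nm = pixel_size_nm,
                 threshold = 1),
            class = "cluster_segmentation")
}
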