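# Shared fixtures and independent oracles, all built in code at test time.

# Rasterized filled disc / axis-aligned ellipse masks.
disc_mask <- function(n = 41L, r = 15, center = c((n + 1) / 2, (n + 1) / 2)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

ellipse_mask_fixture <- function(n = 61L, a = 24, b = 12) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  ((rows - c0) / b)^2 + ((cols - c0) / a)^2 <= 1
}

# Brute-force 'same' cross-correlation: direct four-nested-loop evaluation of
# out(i,j) = sum_{n,m} B(i+n-pr, j+m-pc) K(n,m), zeros outside B.
oracle_cross_correlation <- function(B, K) {
  kh <- nrow(K); kw <- ncol(K)
  pr <- (kh - 1) %/% 2; pc <- (kw - 1) %/% 2
  out <- matrix(0, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      acc <- 0
      for (n in seq_len(kh)) {
        for (m in seq_len(kw)) {
          r <- i + n - 1L - pr; c <- j + m - 1L - pc
          if (r >= 1 && r <= nrow(B) && c >= 1 && c <= ncol(B)) {
            acc <- acc + B[r, c] * K[n, m]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Window-by-window max-pool enumeration.
oracle_maxpool <- function(m, kernel = 2L, stride = 2L) {
  ho <- (nrow(m) - kernel) %/% stride + 1L
  wo <- (ncol(m) - kernel) %/% stride + 1L
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      r <- (i - 1L) * stride + 1L; c <- (j - 1L) * stride + 1L
      out[i, j] <- max(m[r:(r + kernel - 1L), c:(c + kernel - 1L)])
    }
  }
  out
}

# Flood fill over the thresholded indicator image |img - img[seed]| <= thr,
# plain R breadth-first search; union over seeds.
oracle_region_grow <- function(img, seeds, thr, connectivity = 8L) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    g <- g[g$dr != 0 | g$dc != 0, ]
    lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i]))
  }
  for (s in seq_len(nrow(seeds))) {
    sr <- seeds[s, 1] + 1L; sc <- seeds[s, 2] + 1L
    ok <- abs(img - img[sr, sc]) <= thr
    seen <- matrix(FALSE, h, w)
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      out[p[1], p[2]] <- TRUE
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && !seen[r, c] && ok[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  out
}

# Definitional 2-D DCT-II (orthonormal) by direct summation.
oracle_dct2 <- function(X) {
  n <- nrow(X)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      cu <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
      cv <- if (v == 0) sqrt(1 / n) else sqrt(2 / n)
      acc <- 0
      for (i in 0:(n - 1)) {
        for (j in 0:(n - 1)) {
          acc <- acc + X[i + 1, j + 1] *
            cos(pi * (2 * i + 1) * u / (2 * n)) *
            cos(pi * (2 * j + 1) * v / (2 * n))
        }
      }
      out[u + 1, v + 1] <- cu * cv * acc
    }
  }
  out
}

# Mann-Whitney AUC by pair counting, ties at half weight.
oracle_auc <- function(labels, scores, positive = "malignant") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Small shared synthetic pair at a fixed seed.
tiny_case_pair <- function(seed = 11L, size = 64L) {
  list(
    benign = generate_case(synth_params("benign",
                                        image_size = c(size, size),
                                        seed = seed)),
    malignant = generate_case(synth_params("malignant",
                                           image_size = c(size, size),
                                           seed = seed)))
}
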