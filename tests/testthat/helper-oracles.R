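# Independent brute-force reference implementations.  These recompute each
# descriptor from its definition with plain double loops and stay
# deliberately separate from the package's vectorized/compiled code paths.

random_gray <- function(M, N, seed) {
  set.seed(seed)
  matrix(sample(0L:255L, M * N, replace = TRUE), M, N)
}

# Disk sums of a centered magnitude spectrum: entry g is the sum of all
# bins within Euclidean distance g of the center (center included).
oracle_disk_sums <- function(mag, center, G) {
  out <- numeric(G)
  for (g in seq_len(G)) {
    s <- 0
    for (i in seq_len(nrow(mag))) {
      for (j in seq_len(ncol(mag))) {
        if (sqrt((i - center[1])^2 + (j - center[2])^2) <= g) {
          s <- s + mag[i, j]
        }
      }
    }
    out[g] <- s
  }
  out
}

# Ring-wedge sector sums: annuli (r_{k-1}, r_k], wedges [k*pi/4, ...)
# from the +u axis counterclockwise, DC excluded, ring-major order.
oracle_sector_sums <- function(mag, center, radii, n_angles) {
  out <- numeric(length(radii) * n_angles)
  wedge_width <- 2 * pi / n_angles
  for (i in seq_len(nrow(mag))) {
    for (j in seq_len(ncol(mag))) {
      du <- j - center[2]
      dv <- -(i - center[1])
      d <- sqrt(du^2 + dv^2)
      if (d == 0 || d > max(radii)) next
      ring <- which(d <= radii)[1]
      if (ring > 1 && d <= radii[ring - 1]) next  # defensive; cannot happen
      ang <- atan2(dv, du) %% (2 * pi)
      wedge <- min(floor(ang / wedge_width), n_angles - 1)
      out[(ring - 1) * n_angles + wedge + 1] <-
        out[(ring - 1) * n_angles + wedge + 1] + mag[i, j]
    }
  }
  out
}

# Scalar (non-vectorized) corrosion automaton: synchronous updates, Moore
# 8-neighborhood with in-grid truncation at the borders.
oracle_cita <- function(grid, v, gamma, iters) {
  M <- nrow(grid)
  N <- ncol(grid)
  cur <- grid
  mass <- numeric(iters)
  total <- 0
  for (t in seq_len(iters)) {
    nxt <- cur
    for (i in seq_len(M)) {
      for (j in seq_len(N)) {
        mn <- Inf
        for (ii in max(1, i - 1):min(M, i + 1)) {
          for (jj in max(1, j - 1):min(N, j + 1)) {
            if (ii == i && jj == j) next
            if (cur[ii, jj] < mn) mn <- cur[ii, jj]
          }
        }
        d <- cur[i, j] - mn
        if (d > v) {
          C <- as.integer(floor(gamma * d))
          nxt[i, j] <- cur[i, j] - C
          total <- total + C
        }
      }
    }
    cur <- nxt
    mass[t] <- total
  }
  list(grid = cur, mass = mass)
}

# Per-pixel LBP histogram, P = 8, R = 1, neighbor 0 east then
# counterclockwise; bit set when neighbor >= center.
oracle_lbp_hist <- function(img) {
  di <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dj <- c(1, 1, 0, -1, -1, -1, 0, 1)
  h <- numeric(256)
  for (i in 2:(nrow(img) - 1)) {
    for (j in 2:(ncol(img) - 1)) {
      code <- 0
      for (p in 1:8) {
        if (img[i + di[p], j + dj[p]] >= img[i, j]) {
          code <- code + 2^(p - 1)
        }
      }
      h[code + 1] <- h[code + 1] + 1
    }
  }
  h
}

# Leading eigenvectors of the sample covariance by power iteration with
# deflation (independent check of the PCA route).
oracle_top_eigvecs <- function(x, k, iters = 2000) {
  xc <- sweep(x, 2, colMeans(x), "-")
  S <- crossprod(xc) / (nrow(x) - 1)
  vecs <- matrix(0, ncol(x), k)
  for (comp in seq_len(k)) {
    v <- rep(1, ncol(S)) / sqrt(ncol(S))
    for (it in seq_len(iters)) {
      v2 <- S %*% v
      v2 <- v2 / sqrt(sum(v2^2))
      if (max(abs(v2 - v)) < 1e-12) { v <- v2; break }
      v <- v2
    }
    vecs[, comp] <- v
    lam <- as.numeric(t(v) %*% S %*% v)
    S <- S - lam * tcrossprod(v)
  }
  vecs
}
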