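# Independent brute-force oracles used to pin down expected values.

# 8-corner weighted sum at one continuous voxel coordinate (0-based).
oracle_trilinear1 <- function(vol, p) {
  d <- dim(vol)
  if (any(p < 0) || any(p > d - 1)) return(0)
  i0 <- pmin(floor(p), d - 2)
  f <- p - i0
  s <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[1] else 1 - f[1]) * (if (dj) f[2] else 1 - f[2]) *
      (if (dk) f[3] else 1 - f[3])
    s <- s + w * vol[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1]
  }
  s
}

# Voxel-set Dice for one code.
oracle_dice <- function(m, a, code) {
  sm <- which(m == code)
  sa <- which(a == code)
  if (length(sm) + length(sa) == 0) return(1)
  2 * length(intersect(sm, sa)) / (length(sm) + length(sa))
}

# Pearson correlation from raw sums (independent of stats::cor).
oracle_cor <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# NMI from explicit histogram entropies.
oracle_nmi <- function(a, b, bins = 32) {
  ix <- function(x) {
    r <- range(x)
    pmin(pmax(floor((x - r[1]) / diff(r) * bins) + 1L, 1L), bins)
  }
  tab <- table(factor(ix(a), levels = 1:bins), factor(ix(b), levels = 1:bins))
  p <- tab / sum(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (h(rowSums(p)) + h(colSums(p))) / h(p)
}

# Scalar-loop normalized surface deviation (matching o_surface's contract).
oracle_o_surface <- function(true_f, est_f, sd) {
  acc <- 0
  for (v in seq_len(nrow(true_f)))
    for (f in seq_len(ncol(true_f)))
      acc <- acc + abs(true_f[v, f] - est_f[v, f]) / max(sd[v, f], 1e-6)
  -acc / length(true_f)
}

# Per-node loop smoothness penalty of a lattice array (n1 x n2 x n3 x 3).
oracle_smoothness <- function(lat) {
  n <- dim(lat)[1:3]
  tot <- 0
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3])
    for (c in 1:3) {
      l <- 0
      if (i > 1) l <- l + lat[i - 1, j, k, c] - lat[i, j, k, c]
      if (i < n[1]) l <- l + lat[i + 1, j, k, c] - lat[i, j, k, c]
      if (j > 1) l <- l + lat[i, j - 1, k, c] - lat[i, j, k, c]
      if (j < n[2]) l <- l + lat[i, j + 1, k, c] - lat[i, j, k, c]
      if (k > 1) l <- l + lat[i, j, k - 1, c] - lat[i, j, k, c]
      if (k < n[3]) l <- l + lat[i, j, k + 1, c] - lat[i, j, k, c]
      tot <- tot + l^2
    }
  tot / prod(n)
}

# Gnomonic-projection barycentric interpolation oracle: loop over all faces,
# solve the 3x3 system, pick the containing face.
oracle_spherical_interp <- function(values, dirs, level) {
  ico <- icosphere(level)
  out <- numeric(nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    best <- -Inf; val <- NA
    for (f in seq_len(nrow(ico$faces))) {
      tri <- ico$faces[f, ]
      A <- t(ico$vertices[tri, ])
      w <- tryCatch(solve(A, dirs[i, ]), error = function(e) NULL)
      if (is.null(w)) next
      if (sum(w) <= 0) next
      w <- w / sum(w)
      if (min(w) > best) {
        best <- min(w)
        val <- sum(w * values[tri])
      }
    }
    out[i] <- val
  }
  out
}

# Triple-loop texture features at given vertices (world mm == voxel coords
# assumed: identity affine, 1 mm spacing).
oracle_features <- function(vol, label_codes, verts, vcodes) {
  d <- dim(vol)
  # independent central-difference gradient magnitude
  gm <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    il <- max(i - 1, 1); ih <- min(i + 1, d[1])
    jl <- max(j - 1, 1); jh <- min(j + 1, d[2])
    kl <- max(k - 1, 1); kh <- min(k + 1, d[3])
    gx <- (vol[ih, j, k] - vol[il, j, k]) / (ih - il)
    gy <- (vol[i, jh, k] - vol[i, jl, k]) / (jh - jl)
    gz <- (vol[i, j, kh] - vol[i, j, kl]) / (kh - kl)
    gm[i, j, k] <- sqrt(gx^2 + gy^2 + gz^2)
  }
  out <- matrix(0, nrow(verts), 9)
  for (vi in seq_len(nrow(verts))) {
    p <- verts[vi, ]
    n0 <- round(p)
    for (ri in 1:3) {
      r <- c(3, 5, 7)[ri]
      irs <- c(); ors <- c(); gs <- c()
      for (ox in -(r + 1):(r + 1)) for (oy in -(r + 1):(r + 1))
        for (oz in -(r + 1):(r + 1)) {
          q <- n0 + c(ox, oy, oz)
          if (sqrt(sum((q - p)^2)) > r) next
          inb <- all(q >= 0) && all(q <= d - 1)
          val <- if (inb) vol[q[1] + 1, q[2] + 1, q[3] + 1] else 0
          gval <- if (inb) gm[q[1] + 1, q[2] + 1, q[3] + 1] else 0
          inside <- inb && label_codes[q[1] + 1, q[2] + 1, q[3] + 1] == vcodes[vi]
          if (inside) irs <- c(irs, val) else ors <- c(ors, val)
          gs <- c(gs, gval)
        }
      if (length(irs) == 0 || length(ors) == 0) {
        out[vi, ri] <- 0; out[vi, 3 + ri] <- 0
      } else {
        sdir <- sqrt(mean(irs^2) - mean(irs)^2)
        out[vi, ri] <- mean(irs) / max(sdir, 1e-6)
        out[vi, 3 + ri] <- 2 * (mean(ors) - mean(irs)) /
          (mean(ors) + mean(irs))
      }
      out[vi, 6 + ri] <- mean(gs)
    }
  }
  out
}
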