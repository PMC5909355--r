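# Independent oracles used to freeze expected values. These deliberately use
# naive enumeration / quadrature, not the package's own code paths.

# Brute-force GLCM: explicit triple loop over voxels and the 13 offsets.
glcm_bruteforce <- function(vals, mask, levels = 8L, displacement = 1L) {
  rng <- range(vals[mask])
  q <- array(0L, dim = dim(vals))
  q[mask] <- pmin(as.integer(floor((vals[mask] - rng[1]) / diff(rng) * levels)) + 1L, levels)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  offs <- offs * displacement
  d <- dim(vals)
  M <- matrix(0, levels, levels)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!mask[i, j, k]) next
      i2 <- i + o[1]; j2 <- j + o[2]; k2 <- k + o[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      if (!mask[i2, j2, k2]) next
      a <- q[i, j, k]; b <- q[i2, j2, k2]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M / sum(M)
}

# Direct-summation Haralick features with explicit loops (log base 2).
haralick_oracle <- function(P) {
  ng <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- 0; for (i in 1:ng) mu_x <- mu_x + i * px[i]
  mu_y <- 0; for (j in 1:ng) mu_y <- mu_y + j * py[j]
  sd_x <- 0; for (i in 1:ng) sd_x <- sd_x + (i - mu_x)^2 * px[i]; sd_x <- sqrt(sd_x)
  sd_y <- 0; for (j in 1:ng) sd_y <- sd_y + (j - mu_y)^2 * py[j]; sd_y <- sqrt(sd_y)
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng) # psum index k = i + j; pdiff index = |i-j| + 1
  energy <- 0; entropy <- 0; idm <- 0; corr_num <- 0; ssq <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    energy <- energy + p^2
    entropy <- entropy - p * lg(p)
    idm <- idm + p / (1 + (i - j)^2)
    corr_num <- corr_num + i * j * p
    ssq <- ssq + (i - mu_x)^2 * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  contrast <- 0; for (k in 0:(ng - 1)) contrast <- contrast + k^2 * pdiff[k + 1]
  s_avg <- 0; for (k in 2:(2 * ng)) s_avg <- s_avg + k * psum[k]
  s_var <- 0; for (k in 2:(2 * ng)) s_var <- s_var + (k - s_avg)^2 * psum[k]
  s_ent <- 0; for (k in 2:(2 * ng)) s_ent <- s_ent - psum[k] * lg(psum[k])
  d_mean <- 0; for (k in 0:(ng - 1)) d_mean <- d_mean + k * pdiff[k + 1]
  d_var <- 0; for (k in 0:(ng - 1)) d_var <- d_var + (k - d_mean)^2 * pdiff[k + 1]
  d_ent <- 0; for (k in 0:(ng - 1)) d_ent <- d_ent - pdiff[k + 1] * lg(pdiff[k + 1])
  hx <- 0; for (i in 1:ng) hx <- hx - px[i] * lg(px[i])
  hy <- 0; for (j in 1:ng) hy <- hy - py[j] * lg(py[j])
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  supp <- which(px > 0)
  mcc <- 0
  if (length(supp) >= 2) {
    Q <- matrix(0, length(supp), length(supp))
    for (ai in seq_along(supp)) for (bi in seq_along(supp)) {
      s <- 0
      for (ki in seq_along(supp)) {
        s <- s + P[supp[ai], supp[ki]] * P[supp[bi], supp[ki]] /
          (px[supp[ai]] * py[supp[ki]])
      }
      Q[ai, bi] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }
  correlation <- if (sd_x * sd_y > 0) (corr_num - mu_x * mu_y) / (sd_x * sd_y) else 0
  list(
    energy = energy, contrast = contrast, correlation = correlation,
    sum_of_squares = ssq, inverse_difference_moment = idm,
    sum_average = s_avg, sum_variance = s_var, sum_entropy = s_ent,
    entropy = entropy, difference_variance = d_var, difference_entropy = d_ent,
    imc1 = imc1, imc2 = imc2, max_correlation_coefficient = mcc
  )
}

# Exhaustive-pair Kendall tau-b.
tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx * sy > 0) conc <- conc + 1
    if (sx * sy < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exhaustive-pair AUC with half credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Surface area of the star-shaped surface r(theta, phi) by fine quadrature:
# dS = r * sqrt(r^2 sin^2 t + r_t^2 sin^2 t + r_p^2) dt dp.
sh_area_quadrature <- function(spec, n_theta = 601, n_phi = 1200) {
  th <- seq(0, pi, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  r <- outer(th, ph, function(t, p) ceipr:::surface_radius(spec, t, p))
  dth <- th[2] - th[1]
  dph <- 2 * pi / n_phi
  r_t <- r
  r_t[2:(n_theta - 1), ] <- (r[3:n_theta, ] - r[1:(n_theta - 2), ]) / (2 * dth)
  r_t[1, ] <- (r[2, ] - r[1, ]) / dth
  r_t[n_theta, ] <- (r[n_theta, ] - r[n_theta - 1, ]) / dth
  rp <- cbind(r[, 2:n_phi], r[, 1])
  rm <- cbind(r[, n_phi], r[, 1:(n_phi - 1)])
  r_p <- (rp - rm) / (2 * dph)
  st <- sin(th)
  integrand <- r * sqrt(r^2 * st^2 + r_t^2 * st^2 + r_p^2)
  w <- rep(dth, n_theta); w[c(1, n_theta)] <- dth / 2
  sum(colSums(integrand * w)) * dph
}

# Digital test solids on isotropic or anisotropic grids.
digital_ball <- function(radius_mm, spacing_mm = c(1, 1, 1), pad_vox = 4) {
  n <- ceiling(2 * radius_mm / spacing_mm) + 2 * pad_vox + 1
  ctr <- (n - 1) / 2 * spacing_mm
  d <- as.integer(n)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing_mm[a] - ctr[a])
  dx2 <- array(rep(ax[[1]]^2, times = d[2] * d[3]), dim = d)
  dy2 <- aperm(array(rep(ax[[2]]^2, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  dz2 <- aperm(array(rep(ax[[3]]^2, times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  (dx2 + dy2 + dz2) <= radius_mm^2
}

digital_ellipsoid <- function(semi_mm, spacing_mm = c(1, 1, 1), pad_vox = 4) {
  n <- ceiling(2 * semi_mm / spacing_mm) + 2 * pad_vox + 1
  d <- as.integer(n)
  ctr <- (n - 1) / 2 * spacing_mm
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) * spacing_mm[a] - ctr[a]) / semi_mm[a])
  dx2 <- array(rep(ax[[1]]^2, times = d[2] * d[3]), dim = d)
  dy2 <- aperm(array(rep(ax[[2]]^2, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  dz2 <- aperm(array(rep(ax[[3]]^2, times = d[1] * d[2]), dim = d[c(3, 2, 1)]), c(3, 2, 1))
  (dx2 + dy2 + dz2) <= 1
}

# Thomsen's approximation of the ellipsoid surface area (error < 1.1%).
ellipsoid_area_approx <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}
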