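# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation available so they stay independent of
# the implementation paths they check.

# O(n^2) all-pairs Euclidean distance transform (mm, anisotropic)
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  world <- sweep(idx - 1, 2, spacing, `*`)
  inside <- mask[idx] == 1
  out <- array(0, d)
  if (!any(inside) || all(inside)) {
    if (all(inside)) out[] <- Inf
    return(out)
  }
  bg <- world[!inside, , drop = FALSE]
  for (r in which(inside)) {
    dif <- sweep(bg, 2, world[r, ], `-`)
    out[idx[r, 1], idx[r, 2], idx[r, 3]] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# Two-way ANOVA ICC(A,k) oracle from explicit sums of squares
icc_oracle <- function(x, conf_level = 0.95) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  fv <- msr / mse
  alpha <- 1 - conf_level
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  aa <- k * icc1 / (n * (1 - icc1))
  bb <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  # independent route: Spearman-Brown step-up applied to the single-measure
  # bounds; beyond the step-up pole the bound is not estimable on that side
  sb <- function(r) k * r / (1 + (k - 1) * r)
  l1 <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  lo <- if (l1 > -1 / (k - 1)) sb(l1) else -Inf
  hi <- if (u1 > -1 / (k - 1)) sb(u1) else 1
  list(icc = icc, f = fv, ci = c(lo, hi))
}

# exact two-sided McNemar p by direct binomial-pmf summation
mcnemar_sum_oracle <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  pmf <- dbinom(0:n, n, 0.5)
  lo <- sum(pmf[seq_len(min(b, cc) + 1)])
  hi <- sum(pmf[(max(b, cc) + 1):(n + 1)])
  min(1, 2 * min(lo, hi))
}

# breach oracle: voxelized cylinder must be contained in the mask
voxelized_breach_oracle <- function(cyl, mask) {
  d <- dim(mask$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  world <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  rel <- sweep(world, 2, cyl$entry_point, `-`)
  t <- as.numeric(rel %*% cyl$axis_dir)
  radial <- sqrt(rowSums((rel - t %*% t(cyl$axis_dir))^2))
  in_cyl <- radial <= cyl$radius & t >= 0 & t <= cyl$length
  any(in_cyl & mask$data[idx] == 0)
}

# default scapula-analog + derived products, shared across tests
analog_fixture <- function(seed = 1) {
  ph <- make_scapula_analog(seed = seed)
  mask <- segment_bone(ph$volume)
  list(ph = ph, mask = mask, dmap = distance_map(mask))
}

capsule_fixture <- function(radius = 5, length = 40, axis = c(0, 0, 1)) {
  ph <- make_capsule_phantom(radius, length, axis_dir = axis, spacing = 1)
  mask <- segment_bone(ph$volume)
  list(ph = ph, mask = mask, dmap = distance_map(mask))
}
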