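# Independent brute-force oracles, written as plain per-voxel loops so that
# the vectorised implementations can be checked against them.

oracle_outlier_fraction <- function(data4d, mask, time_s, order = 2,
                                    qthr = 0.001) {
  d <- dim(data4d)
  k <- qnorm(1 - qthr / 2) * sqrt(pi / 2)
  vox <- which(mask, arr.ind = TRUE)
  nt <- d[4]
  flags <- matrix(FALSE, nt, nrow(vox))
  for (i in seq_len(nrow(vox))) {
    y <- data4d[vox[i, 1], vox[i, 2], vox[i, 3], ]
    fit <- lm(y ~ poly(time_s, order))
    r <- residuals(fit)
    m <- median(abs(r))
    thr <- k * m
    flags[, i] <- if (thr == 0) abs(r) > 0 else abs(r) > thr
  }
  rowMeans(flags)
}

oracle_resp_map <- function(data4d, var_pos, stable_pos, mask,
                            units = "raw") {
  d <- dim(data4d)[1:3]
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (!mask[i, j, l]) next
    sm <- mean(data4d[i, j, l, stable_pos])
    devs <- abs(data4d[i, j, l, var_pos] - sm)
    v <- mean(devs)
    if (units == "percent") v <- if (sm > 0) v / sm * 100 else NaN
    out[i, j, l] <- v
  }
  out
}

oracle_profile <- function(vals, depth, roi, n_bins) {
  sel <- which(roi & !is.na(depth) & is.finite(vals))
  b <- pmin(pmax(ceiling(depth[sel] * n_bins), 1), n_bins)
  res <- list()
  for (bin in sort(unique(b))) {
    v <- vals[sel[b == bin]]
    res[[length(res) + 1]] <- data.frame(
      depth_bin = (bin - 0.5) / n_bins,
      mean_pct = mean(v),
      sem_pct = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
      n_vox = length(v))
  }
  do.call(rbind, res)
}

oracle_hist2d <- function(x, y, bins) {
  bx <- seq(min(x), max(x), length.out = bins + 1)
  by <- seq(min(y), max(y), length.out = bins + 1)
  cnt <- matrix(0L, bins, bins)
  for (i in seq_along(x)) {
    ix <- max(1, min(bins, findInterval(x[i], bx, rightmost.closed = TRUE)))
    iy <- max(1, min(bins, findInterval(y[i], by, rightmost.closed = TRUE)))
    cnt[ix, iy] <- cnt[ix, iy] + 1L
  }
  cnt
}

oracle_edt <- function(mask) {
  d <- dim(mask)
  sites <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    dd <- (sites[, 1] - i)^2 + (sites[, 2] - j)^2 + (sites[, 3] - l)^2
    out[i, j, l] <- sqrt(min(dd))
  }
  out
}

oracle_neighbor_corr <- function(data4d, mask, off) {
  d <- dim(data4d)[1:3]
  tot <- 0
  n <- 0L
  tt <- seq_len(dim(data4d)[4])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    i2 <- i + off[1]; j2 <- j + off[2]; l2 <- l + off[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || l2 < 1 || l2 > d[3])
      next
    if (!mask[i, j, l] || !mask[i2, j2, l2]) next
    a <- residuals(lm(data4d[i, j, l, ] ~ tt))
    b <- residuals(lm(data4d[i2, j2, l2, ] ~ tt))
    if (sd(a) == 0 || sd(b) == 0) next
    tot <- tot + cor(a, b)
    n <- n + 1L
  }
  if (n == 0) NA_real_ else tot / n
}

# number of 6-connected components of a 3D logical mask (flood fill)
label_components6 <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  ncomp <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  todo <- which(m)
  while (length(todo) > 0) {
    ncomp <- ncomp + 1L
    frontier <- array(FALSE, d)
    frontier[todo[1]] <- TRUE
    comp <- frontier
    repeat {
      grown <- comp
      for (r in seq_len(nrow(offs))) {
        sh <- laminaresp:::shift3d(comp, offs[r, ], fill = FALSE)
        grown <- grown | (sh & m)
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- ncomp
    todo <- which(m & lab == 0L)
  }
  ncomp
}
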