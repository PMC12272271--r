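#' Neighbor-correlation blurring kernel
#'
#' Effective spatial smoothness of a time series, measured as the mean
#' Pearson correlation of each voxel's time series with its neighbors at
#' every integer offset within `radius`: `K(o)` is the mean over in-mask
#' voxel pairs at offset `o` of the correlation between the two (linearly
#' detrended) series. `K(0) = 1` exactly, and the pairing is symmetric so
#' `K(o) = K(-o)` exactly. Zero-variance voxels are excluded from the pairs.
#'
#' @param series A [volume_series()] or `contrast_series` (uncensored
#'   volumes are used).
#' @param mask 3D logical mask (>= 10 voxels); both members of a pair must
#'   be inside it.
#' @param radius Kernel radius in voxels (default 3, i.e. a 7x7x7 kernel).
#' @param detrend_order Polynomial detrend order applied per voxel before
#'   correlating (default 1).
#' @return A `correlation_kernel`: list with `kernel` (array of side
#'   `2*radius+1`, dimnames = offsets), `counts` (pairs per offset),
#'   `radius`, `n_voxels`.
#' @export
neighbor_correlation_kernel <- function(series, mask, radius = 3,
                                        detrend_order = 1) {
  if (sum(mask) < 10) stop_param("mask has fewer than 10 voxels")
  keep <- which(!(series$censored %||% rep(FALSE, dim(series$data)[4])))
  dat <- series$data[, , , keep, drop = FALSE]
  d3 <- dim(dat)[1:3]
  nt <- length(keep)
  nvox <- prod(d3)
  y <- t(matrix(dat, nvox, nt))                # T x allvox
  y <- detrend_poly(y, detrend_order, series$time_s[keep])
  ss <- sqrt(colSums(y^2))
  raw_norm <- sqrt(rowSums(matrix(dat, nvox, nt)^2))
  valid <- as.vector(mask) & is.finite(ss) & ss > 1e-8 * (raw_norm + 1)
  z <- sweep(y, 2, ifelse(ss > 0, ss, 1), "/")
  z[, !valid] <- 0                             # excluded voxels contribute 0
  zarr <- array(t(z), c(d3, nt))
  varr <- array(valid, d3)

  side <- 2 * radius + 1
  kern <- array(NA_real_, c(side, side, side))
  cnt <- array(0L, c(side, side, side))
  offs <- seq(-radius, radius)
  dimnames(kern) <- dimnames(cnt) <- list(offs, offs, offs)
  slice_ranges <- function(n, o) {
    # index ranges of the overlap when shifting by o along an axis of size n
    if (o >= 0) list(a = seq_len(n - o), b = seq_len(n - o) + o)
    else list(a = seq_len(n + o) - o, b = seq_len(n + o))
  }
  for (oi in offs) for (oj in offs) for (ok in offs) {
    # compute each symmetric pair of offsets once
    key <- c(oi, oj, ok)
    if (!is.na(kern[oi + radius + 1, oj + radius + 1, ok + radius + 1])) next
    rx <- slice_ranges(d3[1], oi)
    ry <- slice_ranges(d3[2], oj)
    rz <- slice_ranges(d3[3], ok)
    n_pairs <- sum(varr[rx$a, ry$a, rz$a] & varr[rx$b, ry$b, rz$b])
    val <- NA_real_
    if (n_pairs > 0) {
      # excluded/out-of-mask voxels are zeroed in zarr, contributing nothing
      tot <- sum(zarr[rx$a, ry$a, rz$a, , drop = FALSE] *
                   zarr[rx$b, ry$b, rz$b, , drop = FALSE])
      val <- tot / n_pairs
    }
    for (s in list(key, -key)) {
      kern[s[1] + radius + 1, s[2] + radius + 1, s[3] + radius + 1] <- val
      cnt[s[1] + radius + 1, s[2] + radius + 1, s[3] + radius + 1] <- n_pairs
    }
  }
  kern[radius + 1, radius + 1, radius + 1] <- 1 # self-correlation, exact
  structure(list(kernel = kern, counts = cnt, radius = radius,
                 n_voxels = sum(valid)), class = "correlation_kernel")
}

#' @export
print.correlation_kernel <- function(x, ...) {
  cat(sprintf("<correlation_kernel> radius %d, %d voxels\n",
              x$radius, x$n_voxels))
  invisible(x)
}

#' FWHM of a blurring kernel along each axis
#'
#' Extracts the axis profiles through the kernel center and measures the full
#' width at half maximum by linear interpolation of the half-maximum
#' crossings; the half-maximum reference is fixed at 0.5 because the central
#' value is identically 1. Profiles that never fall below 0.5 within the
#' kernel radius are reported as `2 * radius` with `censored = TRUE`; a
#' non-monotone profile near the center still uses the first crossing and is
#' flagged.
#'
#' @param kernel A `correlation_kernel`.
#' @return Tibble with columns `axis` (`"x"`, `"y"`, `"z"`), `fwhm` (voxels),
#'   `censored`, `nonmonotone`.
#' @export
kernel_fwhm <- function(kernel) {
  stopifnot(inherits(kernel, "correlation_kernel"))
  r <- kernel$radius
  c0 <- r + 1
  prof <- list(
    x = kernel$kernel[, c0, c0],
    y = kernel$kernel[c0, , c0],
    z = kernel$kernel[c0, c0, ]
  )
  one_side <- function(p) {
    # p: values at offsets 0..r
    below <- which(!is.na(p) & p < 0.5)
    if (length(below) == 0)
      return(list(hw = r, censored = TRUE, nonmono = FALSE))
    i <- min(below)                     # first crossing
    nonmono <- any(diff(p[seq_len(i)]) > 0)
    hw <- (i - 2) + (p[i - 1] - 0.5) / (p[i - 1] - p[i])
    list(hw = hw, censored = FALSE, nonmono = nonmono)
  }
  rows <- lapply(names(prof), function(ax) {
    p <- prof[[ax]]
    pos <- one_side(p[c0:(c0 + r)])
    neg <- one_side(p[c0:(c0 - r)])
    tibble::tibble(axis = ax,
                   fwhm = unname(pos$hw + neg$hw),
                   censored = pos$censored || neg$censored,
                   nonmonotone = pos$nonmono || neg$nonmono)
  })
  do.call(rbind, rows)
}

#' Write kernel axis profiles and FWHM as TSV
#'
#' @param kernel A `correlation_kernel`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_kernel_profiles <- function(kernel, path) {
  r <- kernel$radius
  c0 <- r + 1
  offs <- seq(-r, r)
  fw <- kernel_fwhm(kernel)
  tab <- data.frame(
    offset = rep(offs, 3),
    axis = rep(c("x", "y", "z"), each = length(offs)),
    correlation = c(kernel$kernel[, c0, c0], kernel$kernel[c0, , c0],
                    kernel$kernel[c0, c0, ]),
    fwhm = rep(fw$fwhm, each = length(offs))
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
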