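# Internal array helpers shared across modules.

#' Exact 3D Euclidean distance transform
#'
#' Distance from every voxel centre to the nearest `TRUE` voxel centre, in
#' `spacing` units. Voxels of the mask itself have distance 0; if the mask is
#' empty all distances are `Inf`.
#'
#' @param mask 3D logical array.
#' @param spacing Numeric length-3 voxel size along x, y, z (default 1,
#'   i.e. distances in voxel units).
#' @return 3D numeric array of distances.
#' @export
edt3d <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  .edt3d_cpp(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
}

# Shift a 3D array by integer offset, padding with `fill`.
shift3d <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected binary dilation, `iter` iterations.
dilate6 <- function(mask, iter = 1) {
  m <- mask
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(iter)) {
    grown <- m
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift3d(m, offs[r, ], fill = FALSE)
    m <- grown
  }
  m
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels, truncated at
# 4 sigma, kernel normalised to unit sum). sigma may be length 1 or 3.
gaussian_smooth3d <- function(a, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    # dense convolution matrix (zero boundary)
    cm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      cm[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    ap <- cm %*% matrix(ap, nrow = n)
    dim(ap) <- dm
    a <- aperm(ap, order(perm))
  }
  a
}

# Flatten a 4D array to a T x V matrix restricted to mask voxels.
mat_from_4d <- function(data4d, mask) {
  d <- dim(data4d)
  m <- matrix(data4d, nrow = prod(d[1:3]), ncol = d[4])
  t(m[as.vector(mask), , drop = FALSE])
}

# Residuals after ordinary polynomial detrending (order >= 0) of the columns
# of a T x V matrix, at time points `tt`.
detrend_poly <- function(y, order, tt = seq_len(nrow(y))) {
  x <- if (order >= 1) cbind(1, stats::poly(tt, degree = order)) else
    matrix(1, nrow(y), 1)
  qr_x <- qr(x)
  y - x %*% qr.coef(qr_x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
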