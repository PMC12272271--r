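#' Tissue segmentation labels
#'
#' Wraps a 3D integer label volume with the code convention used throughout
#' the package: 0 = background, 1 = WM, 2 = GM, 3 = CSF. GM is expected to
#' form a shell touching both WM and the CSF/background side.
#'
#' @param labels 3D integer array.
#' @param voxel_mm Voxel size in mm (length 1 or 3).
#' @return A `seg_labels` object.
#' @export
seg_labels <- function(labels, voxel_mm = 1) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (!all(unique(as.vector(labels)) %in% 0:3))
    stop_param("labels must take values in {0 background, 1 WM, 2 GM, 3 CSF}")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  structure(list(labels = labels, voxel_mm = voxel_mm), class = "seg_labels")
}

LBL_BG <- 0L; LBL_WM <- 1L; LBL_GM <- 2L; LBL_CSF <- 3L

gm_mask <- function(seg) seg$labels == LBL_GM

#' Equi-volume cortical depth
#'
#' Computes the laminar coordinate on a volumetric segmentation. First an
#' equidistant depth is formed from the Euclidean distance transforms of each
#' GM voxel to the WM and the CSF/background boundaries (distances measured
#' to boundary faces via a half-voxel offset): `delta = d_csf / (d_csf +
#' d_wm)`, 0 at the CSF side and 1 at the WM side, matching the CSF -> WM
#' orientation of reported profiles. Then, within each cortical column, the
#' equi-volume depth of a voxel is the cumulative tissue-volume fraction of
#' the column below it when voxels are sorted by equidistant depth — the
#' discrete volume-fraction (equi-volume) construction, which corrects the
#' equidistant coordinate for cortical curvature.
#'
#' @param seg A [seg_labels()].
#' @param columns Optional precomputed [build_columns()] labels used for the
#'   cumulative-volume step; by default a fine parcellation with about
#'   `fine_voxels_per_column` voxels per column is built internally.
#' @param fine_voxels_per_column Target column size for the internal
#'   parcellation (default 500; smaller columns have noisier cross-section
#'   profiles and degrade the volume-fraction depth).
#' @param seed Seed for the internal parcellation (default 1).
#' @return A `depth_map`: list with 3D `equivol` and `equidist` arrays (`NA`
#'   outside GM), the `columns` used, and `n_undefined` (GM voxels without a
#'   defined depth, excluded with a warning).
#' @export
equivolume_depth <- function(seg, columns = NULL,
                             fine_voxels_per_column = 500, seed = 1) {
  stopifnot(inherits(seg, "seg_labels"))
  gm <- gm_mask(seg)
  if (!any(gm)) stop_param("no GM voxels")
  wm <- seg$labels == LBL_WM
  outer <- seg$labels == LBL_CSF | seg$labels == LBL_BG
  if (!any(wm) || !any(outer))
    stop_param("GM must touch both a WM and a CSF/background boundary")
  d_wm <- pmax(edt3d(wm) - 0.5, 1e-6)
  d_csf <- pmax(edt3d(outer) - 0.5, 1e-6)
  delta <- array(NA_real_, dim(gm))
  delta[gm] <- d_csf[gm] / (d_csf[gm] + d_wm[gm])
  undef <- gm & (!is.finite(d_wm) | !is.finite(d_csf))
  n_undefined <- sum(undef)
  if (n_undefined > 0) {
    warning(n_undefined, " GM voxels have no path to both boundaries; excluded")
    delta[undef] <- NA_real_
  }

  if (is.null(columns)) {
    k <- max(1L, round(sum(gm & !undef) / fine_voxels_per_column))
    columns <- build_columns(seg, delta, K = k, seed = seed)
  }
  lab <- if (inherits(columns, "column_labels")) columns$labels else columns

  equivol <- array(NA_real_, dim(gm))
  idx <- which(gm & !is.na(delta) & !is.na(lab) & lab > 0)
  spl <- split(idx, lab[idx])
  for (vox in spl) {
    n <- length(vox)
    ord <- order(delta[vox])
    # equal voxel volumes: mid-point cumulative volume fraction, CSF -> WM
    equivol[vox[ord]] <- (seq_len(n) - 0.5) / n
  }
  structure(list(equivol = equivol, equidist = delta, columns = columns,
                 n_undefined = n_undefined), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %d GM voxels, %d undefined\n",
              sum(!is.na(x$equivol)), x$n_undefined))
  invisible(x)
}

#' Parcellate gray matter into columns/nodes
#'
#' Seeds are chosen by farthest-point sampling on the mid-depth shell
#' (equidistant depth in `[0.4, 0.6]`). The mid-shell voxels are assigned to
#' their geodesically nearest seed (distances on the 6-connected within-GM
#' voxel graph, so columns never leak across sulci), and the labels are then
#' propagated outward through the GM graph, so that every voxel joins the
#' column of its nearest mid-depth patch. Propagating from the mid-depth
#' patch (rather than from the seed point) makes columns follow the cortical
#' normal — wedge-shaped on curved cortex — which is what lets the
#' cumulative-volume depth correct for curvature. The seeded sampling makes
#' the parcellation reproducible.
#'
#' @param seg A [seg_labels()].
#' @param depth Equidistant depth (3D array, or a `depth_map` whose
#'   `equidist` is used) defining the mid-depth shell.
#' @param K Number of columns (>= 1). The whole-brain analyses of the method
#'   use K = 1000; on phantom sectors keep at least ~30 voxels per node.
#' @param seed RNG seed for the farthest-point start (default 1).
#' @return A `column_labels`: list with 3D integer `labels` (`NA` outside
#'   GM), `K`, seed voxel indices, and the coefficient of variation of node
#'   sizes (`size_cv`).
#' @export
build_columns <- function(seg, depth, K, seed = 1) {
  stopifnot(inherits(seg, "seg_labels"), K >= 1)
  if (inherits(depth, "depth_map")) depth <- depth$equidist
  gm <- gm_mask(seg)
  gm_idx <- which(gm)
  nv <- length(gm_idx)
  if (K == 1) {
    lab <- array(NA_integer_, dim(gm))
    lab[gm] <- 1L
    return(structure(list(labels = lab, K = 1L, seeds = gm_idx[1],
                          size_cv = 0), class = "column_labels"))
  }
  cand <- gm & !is.na(depth) & depth >= 0.4 & depth <= 0.6
  # thin the mid band to a locally one-voxel layer so that columns project
  # coherently from both sides: drop a candidate when a 6-neighbor candidate
  # is strictly closer to mid-depth (ties broken toward the CSF side)
  score <- abs(depth - 0.5)
  keep <- cand
  offs6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (rI in seq_len(nrow(offs6))) {
    nc <- shift3d(cand, offs6[rI, ], fill = FALSE)
    ns <- shift3d(score, offs6[rI, ], fill = NA_real_)
    nd <- shift3d(depth, offs6[rI, ], fill = NA_real_)
    drop <- cand & nc & !is.na(ns) &
      (ns < score | (ns == score & nd < depth))
    keep <- keep & !drop
  }
  mid <- which(keep)
  if (length(mid) == 0) mid <- which(cand)
  if (K > length(mid))
    stop_param("K (", K, ") exceeds mid-shell voxel count (", length(mid), ")")

  dmn <- dim(gm)
  coords <- arrayInd(mid, dmn)
  # farthest-point sampling in Euclidean coordinates on the mid shell
  seeds <- integer(K)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  seeds[1] <- sample.int(length(mid), 1)
  dmin <- rowSums((coords - rep(coords[seeds[1], ], each = nrow(coords)))^2)
  if (K >= 2) for (k in 2:K) {
    seeds[k] <- which.max(dmin)
    dk <- rowSums((coords - rep(coords[seeds[k], ], each = nrow(coords)))^2)
    dmin <- pmin(dmin, dk)
  }
  seed_vox <- mid[seeds]

  # 6-connected within-GM graph: label the mid shell by nearest seed
  g <- gm_graph(gm)
  seed_ids <- match(seed_vox, gm_idx)
  mid_ids <- match(mid, gm_idx)
  dist <- igraph::distances(g, v = seed_ids, to = mid_ids,
                            algorithm = "unweighted") # K x n_mid
  mid_lab <- max.col(-t(dist), ties.method = "first")
  unreach <- !is.finite(dist[cbind(mid_lab, seq_along(mid_ids))])
  if (any(unreach)) {
    # mid-shell voxels in a component with no seed: Euclidean nearest seed
    cs <- coords[seeds, , drop = FALSE]
    for (j in which(unreach)) {
      d2 <- rowSums((cs - rep(coords[j, ], each = K))^2)
      mid_lab[j] <- which.min(d2)
    }
  }
  mid_lab_full <- array(NA_integer_, dmn)
  mid_lab_full[mid] <- mid_lab

  # assign every GM voxel to the column of its Euclidean-nearest mid-shell
  # voxel (exact feature transform), i.e. project along the cortical normal
  mid_mask <- array(FALSE, dmn)
  mid_mask[mid] <- TRUE
  ft <- .edt3d_ft_cpp(mid_mask, as.integer(dmn), c(1, 1, 1))
  lab <- array(NA_integer_, dmn)
  lab[gm_idx] <- mid_lab_full[ft$index[gm_idx]]
  assign_lab <- lab[gm_idx]
  sizes <- tabulate(assign_lab, nbins = K)
  structure(list(labels = lab, K = as.integer(K), seeds = seed_vox,
                 size_cv = sd(sizes) / mean(sizes)),
            class = "column_labels")
}

#' @export
print.column_labels <- function(x, ...) {
  cat(sprintf("<column_labels> K=%d, node-size CV %.3f\n", x$K, x$size_cv))
  invisible(x)
}

# igraph of GM voxels, 6-connected.
gm_graph <- function(gm) {
  gm_idx <- which(gm)
  id <- array(NA_integer_, dim(gm))
  id[gm_idx] <- seq_along(gm_idx)
  edges <- list()
  for (ax in 1:3) {
    off <- c(0, 0, 0); off[ax] <- 1
    nb <- shift3d(id, -off, fill = NA_integer_) # neighbor at +1 along ax
    both <- !is.na(id) & !is.na(nb)
    edges[[ax]] <- cbind(id[both], nb[both])
  }
  e <- do.call(rbind, edges)
  igraph::make_graph(as.vector(t(e)), n = length(gm_idx), directed = FALSE)
}

#' Construct an analysis ROI from seed labels
#'
#' The seed region is dilated (6-connected, iteratively), re-intersected with
#' GM, and optionally restricted to voxels showing activation of the required
#' sign at an uncorrected p threshold — the construction used for the V1
#' region, where the identical ROI is reused for the BOLD and VAPER profiles.
#'
#' @param roi_labels 3D logical seed mask (e.g. an atlas region transformed
#'   to volume space).
#' @param seg A [seg_labels()] providing the GM mask.
#' @param activation Optional `activation_map` (see [fit_block_glm()]) used
#'   for the activation restriction.
#' @param dilation_voxels Dilation iterations (default 2).
#' @param p_threshold Uncorrected p threshold (default 0.01).
#' @param sign `"positive"` (default) or `"negative"` activation required.
#' @return 3D logical ROI mask.
#' @export
build_roi <- function(roi_labels, seg, activation = NULL,
                      dilation_voxels = 2, p_threshold = 0.01,
                      sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(inherits(seg, "seg_labels"))
  if (!any(roi_labels)) stop_param("empty ROI: seed mask has no voxels")
  roi <- dilate6(roi_labels, dilation_voxels)
  roi <- roi & gm_mask(seg)
  if (!any(roi))
    stop_param("empty ROI: dilated seed does not intersect GM")
  if (!is.null(activation)) {
    ok <- activation$p < p_threshold &
      (if (sign == "positive") activation$beta > 0 else activation$beta < 0)
    ok[!is.finite(activation$p)] <- FALSE
    roi <- roi & ok
    if (!any(roi))
      stop_param("empty ROI: activation constraint (p < ", p_threshold,
                 ", ", sign, ") removed all voxels")
  }
  roi
}
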