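#' Volume series: the 4D carrier between pipeline stages
#'
#' A `volume_series` bundles a 4D intensity array with its affine, repetition
#' time, per-volume condition labels (`"control"`, `"nulled"`, `"mt"` or
#' `"none"`), a per-volume censor flag and acquisition metadata. It is the
#' object every stage of the pipeline consumes and produces.
#'
#' @param data 4D numeric array (x, y, z, t); all values must be finite.
#' @param tr_s Repetition time per volume in seconds (> 0).
#' @param condition Character vector of per-volume labels, one of
#'   `"control"`, `"nulled"`, `"mt"`, `"none"`. Recycled if length 1.
#' @param censored Logical per-volume censor flags (default all `FALSE`).
#' @param affine 4x4 voxel-to-world transform in mm (default: scaled identity
#'   from `voxel_mm`).
#' @param time_s Acquisition start time of each volume in seconds (default
#'   `(0:(T-1)) * tr_s`).
#' @param time_index Indices of the volumes in their original parent run
#'   (default `1:T`); preserved when conditions are split so that downstream
#'   stages can refer back to the acquisition grid.
#' @param voxel_mm Voxel size in mm (length 1 or 3), metadata only.
#' @param meta List of additional acquisition metadata (e.g. `te_ms`).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr_s, condition = "none", censored = NULL,
                          affine = NULL, time_s = NULL, time_index = NULL,
                          voxel_mm = 1, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (any(!is.finite(data)))
    stop_param("volume series contains non-finite values")
  nt <- dim(data)[4]
  if (!is.numeric(tr_s) || length(tr_s) != 1 || tr_s <= 0)
    stop_param("tr_s must be a single positive number")
  condition <- rep_len(as.character(condition), nt)
  bad <- setdiff(unique(condition), c("control", "nulled", "mt", "none"))
  if (length(bad) > 0)
    stop_param("unknown condition labels: ", paste(bad, collapse = ", "))
  censored <- if (is.null(censored)) rep(FALSE, nt) else as.logical(censored)
  if (length(censored) != nt)
    stop_param("censored must have one flag per volume")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(
    data = data,
    affine = affine,
    tr_s = tr_s,
    condition = condition,
    censored = censored,
    time_s = time_s %||% ((seq_len(nt) - 1) * tr_s),
    time_index = as.integer(time_index %||% seq_len(nt)),
    meta = c(meta, list(voxel_mm = voxel_mm))
  ), class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d, %d volumes, TR %.3f s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat("  conditions:",
      paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
            collapse = ", "), "\n")
  cat(sprintf("  censored: %d\n", sum(x$censored)))
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

# Subset a volume_series along time, keeping provenance fields aligned.
subset_volumes <- function(series, idx) {
  out <- series
  out$data <- series$data[, , , idx, drop = FALSE]
  out$condition <- series$condition[idx]
  out$censored <- series$censored[idx]
  out$time_s <- series$time_s[idx]
  out$time_index <- series$time_index[idx]
  out
}

#' Read / write a volume series as NIfTI plus sidecar TSV
#'
#' The image is stored as NIfTI-1 (x, y, z, t; RAS affine respected) and the
#' per-volume condition labels and censor flags as a sidecar TSV with columns
#' `volume_index`, `condition`, `censored`.
#'
#' @param series A [volume_series()].
#' @param nifti_path Path of the `.nii`/`.nii.gz` image.
#' @param sidecar_path Path of the sidecar TSV (default: image path with
#'   `_volumes.tsv` extension).
#' @param tr_s Repetition time override when the NIfTI header lacks one.
#' @return `write_volume_series()` returns the paths invisibly;
#'   `read_volume_series()` returns a [volume_series()].
#' @export
write_volume_series <- function(series, nifti_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% default_sidecar(nifti_path)
  img <- RNifti::asNifti(series$data)
  img <- RNifti::`pixdim<-`(img, c(series$meta$voxel_mm, series$tr_s))
  RNifti::writeNifti(img, nifti_path)
  tab <- data.frame(volume_index = series$time_index,
                    condition = series$condition,
                    censored = as.integer(series$censored))
  write.table(tab, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nifti = nifti_path, sidecar = sidecar_path))
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(nifti_path, sidecar_path = NULL, tr_s = NULL) {
  sidecar_path <- sidecar_path %||% default_sidecar(nifti_path)
  img <- RNifti::readNifti(nifti_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1)
  if (any(!is.finite(data)))
    stop_param("non-finite values in ", nifti_path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  tr_s <- tr_s %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
  tab <- read.delim(sidecar_path, sep = "\t")
  if (nrow(tab) != dim(data)[4])
    stop_param("sidecar row count does not match volume count")
  volume_series(data, tr_s = tr_s,
                condition = tab$condition,
                censored = as.logical(tab$censored),
                affine = structure(RNifti::xform(img), dim = c(4, 4)),
                time_index = tab$volume_index,
                time_s = (tab$volume_index - 1) * tr_s,
                voxel_mm = pd[1:3])
}

default_sidecar <- function(nifti_path) {
  paste0(sub("\\.nii(\\.gz)?$", "", nifti_path), "_volumes.tsv")
}

#' Write a 3D map as NIfTI
#'
#' @param map 3D numeric array.
#' @param path Output path.
#' @param voxel_mm Voxel size in mm (length 1 or 3).
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_mm = 1) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  img <- RNifti::asNifti(map)
  img <- RNifti::`pixdim<-`(img, voxel_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a motion-parameter table
#'
#' Six rigid-body parameters per volume: translations `trans_x/y/z` in mm and
#' rotations `rot_x/y/z` in degrees.
#'
#' @param path TSV file with the six named columns.
#' @return A tibble with one row per volume.
#' @export
read_motion_table <- function(path) {
  tab <- read.delim(path, sep = "\t")
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(tab)))
    stop_param("motion table must have columns ", paste(need, collapse = ", "))
  tibble::as_tibble(tab[, need])
}
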