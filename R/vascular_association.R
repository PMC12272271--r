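#' Per-node vessel density and respiration-effect summaries
#'
#' For every column/node: the vessel density (vessel voxel count divided by
#' node voxel count) and the mean respiration effect. With `normalize = TRUE`
#' (the default) each quantity is divided by its mean across the subject's
#' nodes, removing between-subject scale differences before pooling.
#'
#' @param columns A `column_labels` from [build_columns()].
#' @param resp_map A [respiration_effect_map()] (or bare 3D array).
#' @param vessel_mask 3D logical mask of segmented vessels, co-registered
#'   with the column labels.
#' @param normalize Divide each column of values by its subject-wise mean
#'   across nodes (default `TRUE`).
#' @param subject Subject identifier stored in the table (default `"s1"`).
#' @return A `node_table` tibble: one row per node with columns `subject`,
#'   `node`, `n_voxels`, `vessel_density`, `resp_effect`, `normalized`.
#' @export
node_summaries <- function(columns, resp_map, vessel_mask, normalize = TRUE,
                           subject = "s1") {
  lab <- if (inherits(columns, "column_labels")) columns$labels else columns
  vals <- if (inherits(resp_map, "respiration_effect_map")) resp_map$map else resp_map
  idx <- which(!is.na(lab))
  l <- lab[idx]
  n_vox <- tabulate(l)
  k <- length(n_vox)
  vess <- tabulate(l[vessel_mask[idx]], nbins = k)
  v <- vals[idx]
  fin <- is.finite(v)
  resp <- rep(NA_real_, k)
  agg <- tapply(v[fin], l[fin], mean)
  resp[as.integer(names(agg))] <- as.numeric(agg)
  tab <- tibble::tibble(subject = subject,
                        node = seq_len(k),
                        n_voxels = n_vox,
                        vessel_density = vess / pmax(n_vox, 1),
                        resp_effect = resp)
  tab <- tab[tab$n_voxels > 0, ] # nodes emptied by masking are dropped
  tab$normalized <- FALSE
  if (normalize) {
    for (colname in c("vessel_density", "resp_effect")) {
      mu <- mean(tab[[colname]], na.rm = TRUE)
      if (!is.finite(mu) || mu == 0)
        stop_param("normalization error for subject ", subject,
                   ": mean of ", colname, " across nodes is 0")
      tab[[colname]] <- tab[[colname]] / mu
    }
    tab$normalized <- TRUE
  }
  class(tab) <- c("node_table", class(tab))
  tab
}

#' Pooled node-wise correlation
#'
#' Collates node tables from all subjects and correlates two columns over
#' the pooled rows (pairwise-complete), with an ordinary least-squares line
#' for plotting. Tables should be per-brain normalized (see
#' [node_summaries()]) so that between-subject scale differences do not drive
#' the pooled correlation.
#'
#' @param tables A `node_table` or list of them (one per subject).
#' @param x_col,y_col Column names to correlate (defaults `vessel_density`,
#'   `resp_effect`).
#' @param method `"pearson"` (default) or `"spearman"` — the latter is more
#'   robust to the heavy right tail of respiration maps.
#' @return List with `r`, `n`, `slope`, `intercept`, `method`.
#' @export
pooled_correlation <- function(tables, x_col = "vessel_density",
                               y_col = "resp_effect",
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(tables, "data.frame")) tables <- list(tables)
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  x <- pooled[[x_col]]
  y <- pooled[[y_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_param("fewer than 3 pairwise-complete nodes")
  if (var(x) == 0 || var(y) == 0)
    stop_param("zero variance in ", if (var(x) == 0) x_col else y_col)
  r <- cor(x, y, method = method)
  fit <- lm(y ~ x)
  list(r = unname(r), n = length(x),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       method = method)
}

#' 2D histogram of pooled node values
#'
#' Counts nodes on a regular grid spanning the pooled ranges of two columns:
#' how the nodes are distributed in the plane of vascular density versus
#' respiration-effect strength. Bins are left-closed with the last bin closed
#' on the right, so every value is counted exactly once.
#'
#' @param table A `node_table` or pooled data frame.
#' @param x_col,y_col Column names (defaults `vessel_density`, `resp_effect`).
#' @param bins Number of bins per axis (default 30), or length-2 vector.
#' @return Integer matrix of counts (`bins[1] x bins[2]`) with attributes
#'   `x_breaks`, `y_breaks`.
#' @export
histogram2d <- function(table, x_col = "vessel_density",
                        y_col = "resp_effect", bins = 30) {
  if (length(bins) == 1) bins <- c(bins, bins)
  tab <- as.data.frame(table)
  x <- tab[[x_col]]
  y <- tab[[y_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop_param("empty table")
  bx <- seq(min(x), max(x), length.out = bins[1] + 1)
  by <- seq(min(y), max(y), length.out = bins[2] + 1)
  ix <- bin_index(x, bx)
  iy <- bin_index(y, by)
  counts <- matrix(0L, bins[1], bins[2])
  for (i in seq_along(ix))
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  structure(counts, x_breaks = bx, y_breaks = by)
}

# left-closed bins, last bin right-closed; degenerate range -> bin 1
bin_index <- function(v, breaks) {
  n <- length(breaks) - 1
  if (breaks[1] == breaks[n + 1]) return(rep(1L, length(v)))
  i <- findInterval(v, breaks, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), n)
}

#' Write a node table as TSV
#'
#' @param table A `node_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_node_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
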