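#' Trajectory root-mean-square and maximum error
#'
#' RMSE over the nine non-reference phases,
#' `(1/3) sqrt(sum_ph (Pos_ph^R - Pos_ph^T)^2)` — the 1/3 prefactor is the
#' nine-phase normalization, i.e. the root of the mean squared error — and
#' the maximum absolute per-phase error.
#'
#' @param recon,truth numeric feature positions (mm) for the compared phases
#'   (equal length; the standard protocol compares the 9 phases 10\%-90\%).
#' @return named numeric: `rmse_mm`, `maxe_mm`.
#' @export
trajectory_rmse_maxe <- function(recon, truth) {
  if (length(recon) != length(truth))
    stop("trajectories differ in length", call. = FALSE)
  if (any(!is.finite(recon)) || any(!is.finite(truth)))
    stop("trajectories contain missing positions", call. = FALSE)
  d <- recon - truth
  c(rmse_mm = sqrt(mean(d^2)), maxe_mm = max(abs(d)))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)` with voxel counts as the area surrogate.
#' Returns 1 when both masks are empty (documented convention).
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("grid mismatch between masks", call. = FALSE)
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Relative reconstruction error
#'
#' Default (root form): `sqrt(sum (u_R - u_T)^2 / sum u_T^2) * 100` percent;
#' the literal no-root ratio is available with `root = FALSE`. An optional
#' region of interest restricts both sums.
#'
#' @param recon,truth [vol3d()] (or arrays) on the same grid.
#' @param roi optional logical array restricting the sums.
#' @param root use the root-normalized form (default).
#' @return percentage.
#' @export
relative_error <- function(recon, truth, roi = NULL, root = TRUE) {
  if (!identical(dim(recon)[1:3], dim(truth)[1:3]))
    stop("grid mismatch", call. = FALSE)
  r <- as.double(recon); t <- as.double(truth)
  if (!is.null(roi)) { r <- r[roi]; t <- t[roi] }
  den <- sum(t^2)
  if (den <= 0) stop("zero-norm truth in the ROI", call. = FALSE)
  ratio <- sum((r - t)^2) / den
  100 * if (root) sqrt(ratio) else ratio
}

#' Threshold-based feature trajectory extraction
#'
#' Within a box ROI, each phase volume is binarized at a uniform threshold
#' and the feature edge is located as the extreme foreground coordinate
#' along the chosen axis. With `subvoxel = TRUE` (default) the edge position
#' is refined by linearly interpolating the threshold crossing between the
#' extreme foreground voxel and its background neighbor, averaged over the
#' columns that attain the extreme — giving sub-voxel trajectories on
#' band-limited images.
#'
#' With `method = "mean"`, the per-column threshold crossings are averaged
#' over all ROI columns instead, which is markedly more stable against the
#' voxel-quantization of a curved edge; the same extractor must then be
#' applied to the reference images so the (constant) surface-curvature
#' offset cancels — which is also how trajectories are compared in practice,
#' reading both the reconstruction and the ground-truth ROI through one
#' uniform threshold.
#'
#' @param volumes list of [vol3d()] phase volumes.
#' @param roi list with `xlim`, `ylim`, `zlim` 1-based index ranges.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param threshold uniform binarization threshold.
#' @param extreme `"min"` or `"max"`: which end of the axis is the edge.
#' @param subvoxel interpolate the crossing position.
#' @param method `"extreme"` (single extreme foreground coordinate) or
#'   `"mean"` (average of per-column crossings).
#' @return numeric vector of world positions (mm), `NA` where the ROI
#'   foreground is empty (flagged missing value).
#' @export
extract_trajectory <- function(volumes, roi, axis = "z", threshold,
                               extreme = "min", subvoxel = TRUE,
                               method = c("extreme", "mean")) {
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  extreme <- match.arg(extreme, c("min", "max"))
  method <- match.arg(method)
  vapply(volumes, function(vol) {
    d <- dim(vol)
    if (roi$xlim[1] < 1 || roi$xlim[2] > d[1] ||
        roi$ylim[1] < 1 || roi$ylim[2] > d[2] ||
        roi$zlim[1] < 1 || roi$zlim[2] > d[3])
      stop("ROI outside the volume grid", call. = FALSE)
    sp <- vol_spacing(vol)
    sub <- unclass(vol)[roi$xlim[1]:roi$xlim[2], roi$ylim[1]:roi$ylim[2],
                        roi$zlim[1]:roi$zlim[2], drop = FALSE]
    fg <- sub >= threshold
    if (!any(fg)) return(NA_real_)
    idx_off <- c(roi$xlim[1], roi$ylim[1], roi$zlim[1]) - 1L
    coords_full <- axis_coords(d[ax], sp[ax])
    if (method == "mean") {
      perp <- setdiff(1:3, ax)
      dims <- dim(sub)
      crossings <- c()
      for (a2 in seq_len(dims[perp[1]])) for (b2 in seq_len(dims[perp[2]])) {
        idx <- vector("list", 3)
        idx[[ax]] <- seq_len(dims[ax]); idx[[perp[1]]] <- a2; idx[[perp[2]]] <- b2
        col <- as.vector(do.call(`[`, c(list(sub), idx)))
        fgc <- which(col >= threshold)
        if (!length(fgc)) next
        sel <- if (extreme == "min") min(fgc) else max(fgc)
        nb <- sel + if (extreme == "min") -1L else 1L
        base_mm <- coords_full[sel + idx_off[ax]]
        if (!subvoxel || nb < 1 || nb > dims[ax] || col[nb] >= threshold ||
            col[sel] <= col[nb]) {
          crossings <- c(crossings, base_mm)
        } else {
          frac <- (col[sel] - threshold) / (col[sel] - col[nb])
          sgn <- if (extreme == "min") -1 else 1
          crossings <- c(crossings, base_mm + sgn * frac * sp[ax])
        }
      }
      return(mean(crossings))
    }
    pos_along <- slice.index(sub, ax)
    sel <- if (extreme == "min") min(pos_along[fg]) else max(pos_along[fg])
    full_n <- d[ax]
    coords <- axis_coords(full_n, sp[ax])
    at_extreme <- fg & (pos_along == sel)
    base_mm <- coords[sel + idx_off[ax]]
    if (!subvoxel) return(base_mm)
    nb_sel <- sel + if (extreme == "min") -1L else 1L
    if (nb_sel < 1 || nb_sel > dim(sub)[ax]) return(base_mm)
    sgn <- if (extreme == "min") -1 else 1
    take_slice <- function(a, i) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- i
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    vals_edge <- take_slice(sub, sel)
    vals_nb <- take_slice(sub, nb_sel)
    mask_edge <- take_slice(at_extreme, sel)
    ve <- vals_edge[mask_edge]
    vn <- vals_nb[mask_edge]
    ok <- vn < threshold & ve >= threshold & (ve - vn) > 0
    if (!any(ok)) return(base_mm)
    frac <- (ve[ok] - threshold) / (ve[ok] - vn[ok])   # in [0, 1)
    mean(base_mm + sgn * frac * sp[ax])
  }, numeric(1))
}

shift_mask <- function(m, ax, by, fill = FALSE) {
  d <- dim(m); n <- d[ax]
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[ax]] <- (1 + by):n; src[[ax]] <- 1:(n - by) }
  else { dst[[ax]] <- 1:(n + by); src[[ax]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighborhood erosion/dilation; out-of-grid treated as `fill`
erode_mask <- function(m, fill = TRUE) {
  out <- m
  for (ax in 1:3) for (by in c(1L, -1L))
    out <- out & shift_mask(m, ax, by, fill)
  out
}

dilate_mask <- function(m) {
  out <- m
  for (ax in 1:3) for (by in c(1L, -1L))
    out <- out | shift_mask(m, ax, by, FALSE)
  out
}

#' Automatic lung segmentation of a reconstructed thorax volume
#'
#' Reproducible surrogate for interactive contouring: voxels below the
#' threshold (midpoint of lung and soft-tissue attenuation) form the dark
#' mask; a one-voxel morphological opening breaks the thin dark corridors
#' that reconstruction artifacts can open between the lungs and the outside
#' air; components touching the volume border (outside air) are discarded;
#' every remaining component at least `min_frac` the size of the largest is
#' kept — the two lungs are disjoint components, so a literal
#' single-largest-component rule would drop one of them — and the kept cores
#' are grown back one voxel within the dark mask.
#'
#' @param volume a [vol3d()].
#' @param threshold attenuation threshold (mm^-1).
#' @param min_frac minimum relative component size kept.
#' @return logical array.
#' @export
lung_segment <- function(volume, threshold, min_frac = 0.25) {
  d <- dim(volume)
  dark <- unclass(volume) < threshold
  core <- erode_mask(dark, fill = TRUE)   # outside the grid counts as air
  lab <- cpp_label(as.logical(core), as.integer(d))
  dim(lab) <- d
  if (max(lab) == 0L) return(array(FALSE, d))
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(border_labels)) sizes[border_labels] <- 0L
  if (all(sizes == 0L)) return(array(FALSE, d))
  keep <- which(sizes >= min_frac * max(sizes))
  dilate_mask(array(lab %in% keep, d)) & dark
}
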