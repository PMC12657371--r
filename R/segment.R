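#' Segment PVS from a vesselness map
#'
#' Thresholds the vesselness response inside a region mask and discards
#' 26-connected components smaller than `min_cluster_voxels`. The 26-neighbour
#' connectivity preserves thin oblique tubes that touch only diagonally. The
#' default threshold (0.1) and minimum cluster size (3 voxels) are calibrated
#' on the standard tube phantom and exposed for tuning.
#'
#' @param v A `vesselness_map` (or plain 3D array in \[0, 1\]).
#' @param region_mask Logical 3D array: where to segment (e.g. the atlas
#'   tissue mask or a nucleus mask).
#' @param threshold Vesselness cut-off in (0, 1).
#' @param min_cluster_voxels Minimum component size kept.
#' @return Logical 3D array: the binary PVS mask.
#' @export
segment_pvs <- function(v, region_mask, threshold = 0.1, min_cluster_voxels = 3L) {
  vol <- if (inherits(v, "vesselness_map")) v$v else v
  assert_that(length(dim(vol)) == 3, "`v` must be 3D")
  assert_that(is.logical(region_mask) && identical(dim(region_mask), dim(vol)),
              "`region_mask` must be a logical array matching `v`")
  assert_that(any(region_mask), "`region_mask` is empty")
  assert_that(threshold > 0 && threshold <= 1, "`threshold` must be in (0, 1]")
  mask <- vol >= threshold & region_mask
  if (!any(mask) || min_cluster_voxels <= 1) return(mask)
  lab <- label_components_26(mask)
  sizes <- tabulate(lab[mask])
  keep <- which(sizes >= min_cluster_voxels)
  out <- array(FALSE, dim = dim(mask))
  out[mask] <- lab[mask] %in% keep
  out
}

# 26-connected component labelling via union-find over foreground voxels.
# Returns an integer array: 0 background, 1..k component ids.
label_components_26 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(fg)) return(lab)
  id <- integer(prod(d))
  id[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  parent <- seq_along(fg)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 |
               (offs[, 1] == 0 & (offs[, 2] > 0 |
                                  (offs[, 2] == 0 & offs[, 3] > 0))), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[k, ], nrow(coords), 3, byrow = TRUE)
    valid <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
             nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(valid)) next
    nb_lin <- nb[valid, 1] + (nb[valid, 2] - 1L) * d[1] +
      (nb[valid, 3] - 1L) * d[1] * d[2]
    a <- which(valid)
    b <- id[nb_lin]
    hit <- b > 0L
    a <- a[hit]; b <- b[hit]
    for (j in seq_along(a)) {
      ra <- find_root(a[j]); rb <- find_root(b[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(fg), find_root, integer(1))
  lab[fg] <- match(roots, unique(roots))
  lab
}

#' Region-wise PVS volume fraction
#'
#' For every atlas nucleus and hemisphere (plus left+right totals and the
#' basal-ganglia aggregate of caudate, putamen, pallidum and amygdala) the PVS
#' volume is the voxel count of the PVS mask inside the region times the voxel
#' volume, and the volume fraction is
#' \deqn{VF = 100 \times PVS\ volume / (gray + white\ matter\ volume)}
#' By default the denominator is the whole-brain GM+WM volume for every
#' region, which removes inter-individual brain-size effects;
#' `denominator = "region"` instead normalises by each region's own tissue
#' volume.
#'
#' @param pvs_mask Logical 3D array from [segment_pvs()].
#' @param atlas A [synthetic_atlas()] (or compatible `pvs_atlas`).
#' @param tissue_mask Logical GM+WM mask; defaults to `atlas$tissue`.
#' @param denominator `"whole_brain"` (default) or `"region"`.
#' @return A tibble with columns `region`, `hemisphere`
#'   (left/right/total), `pvs_volume_mm3`, `tissue_volume_mm3`, `vf_percent`.
#' @export
pvs_volume_fraction <- function(pvs_mask, atlas, tissue_mask = NULL,
                                denominator = c("whole_brain", "region")) {
  denominator <- match.arg(denominator)
  assert_that(inherits(atlas, "pvs_atlas"), "`atlas` must be a pvs_atlas")
  tissue_mask <- tissue_mask %||% atlas$tissue
  assert_that(identical(dim(pvs_mask), dim(atlas$labels)) &&
              identical(dim(tissue_mask), dim(atlas$labels)),
              "masks and atlas must share one grid")
  vox_vol <- prod(atlas$voxel_size)
  brain_tissue <- sum(tissue_mask) * vox_vol
  assert_that(brain_tissue > 0, "tissue mask is empty: zero GM+WM volume")

  per_hemi <- atlas$lookup
  per_hemi$pvs_volume_mm3 <- vapply(seq_len(nrow(per_hemi)), function(i) {
    sum(pvs_mask & atlas$labels == per_hemi$code[i]) * vox_vol
  }, numeric(1))
  per_hemi$tissue_volume_mm3 <- if (denominator == "whole_brain") {
    brain_tissue
  } else {
    vapply(per_hemi$code, function(cd) {
      v <- sum(tissue_mask & atlas$labels == cd) * vox_vol
      assert_that(v > 0, "region has zero tissue volume")
      v
    }, numeric(1))
  }

  totals <- per_hemi |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      hemisphere = "total",
      pvs_volume_mm3 = sum(.data$pvs_volume_mm3),
      tissue_volume_mm3 = if (denominator == "whole_brain")
        brain_tissue else sum(.data$tissue_volume_mm3),
      .groups = "drop"
    )
  base <- dplyr::bind_rows(
    dplyr::select(per_hemi, "region", "hemisphere",
                  "pvs_volume_mm3", "tissue_volume_mm3"),
    totals
  )
  bg <- base |>
    dplyr::filter(.data$region %in% BG_SUBDIVISIONS) |>
    dplyr::group_by(.data$hemisphere) |>
    dplyr::summarise(
      region = "BG",
      pvs_volume_mm3 = sum(.data$pvs_volume_mm3),
      tissue_volume_mm3 = if (denominator == "whole_brain")
        brain_tissue else sum(.data$tissue_volume_mm3),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(base, bg)
  out$vf_percent <- 100 * out$pvs_volume_mm3 / out$tissue_volume_mm3
  tibble::as_tibble(out[, c("region", "hemisphere", "pvs_volume_mm3",
                            "tissue_volume_mm3", "vf_percent")])
}
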