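#' Build the synthetic template-space atlas
#'
#' A deterministic, geometry-based stand-in for the subcortical / white-matter
#' label atlases used in lacune-incidence and ROI-masked analyses. Twelve
#' spherical regions are placed inside a spherical brain: putamen, caudate,
#' hippocampus, thalamus, frontal white matter and centrum semiovale, each
#' left/right mirrored (the right-hemisphere label lattice is the exact
#' x-flip of the left, so mirrored regions have identical voxel counts).
#' Label 0 is background; all named regions are non-empty and pairwise
#' disjoint, or the constructor aborts naming the first unplaceable region.
#'
#' @param grid_shape integer length-3 lattice shape.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param space_tag template-space identifier.
#' @return object of class `svd_atlas`: list with `labels` (a [volume()] of
#'   integer labels), `names` (named label vector) and the grid metadata.
#' @export
make_atlas <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 2,
                       space_tag = "template") {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  n <- as.integer(grid_shape)
  # left-hemisphere centres in normalized [0,1] coordinates and radii
  # (fraction of the first grid dimension); right side is the exact mirror
  rois <- list(
    putamen           = list(c = c(0.30, 0.48, 0.50), r = 0.055),
    caudate           = list(c = c(0.38, 0.60, 0.56), r = 0.045),
    hippocampus       = list(c = c(0.30, 0.34, 0.38), r = 0.050),
    thalamus          = list(c = c(0.44, 0.42, 0.50), r = 0.050),
    frontal_wm        = list(c = c(0.34, 0.72, 0.60), r = 0.070),
    centrum_semiovale = list(c = c(0.36, 0.52, 0.74), r = 0.060)
  )
  labels <- array(0L, dim = n)
  ax <- seq_len(n[1]); ay <- seq_len(n[2]); az <- seq_len(n[3])
  name_vec <- integer(0)
  lab <- 0L
  for (nm in names(rois)) {
    ro <- rois[[nm]]
    cc <- ro$c * (n - 1) + 1
    r <- ro$r * n[1]
    d2 <- outer(outer((ax - cc[1])^2, (ay - cc[2])^2, "+"), (az - cc[3])^2, "+")
    m_left <- d2 <= r^2
    if (!any(m_left))
      stop("grid too small to place region '", nm, "_L'")
    m_right <- m_left[rev(ax), , , drop = FALSE]  # exact x mirror
    for (side in c("L", "R")) {
      m <- if (side == "L") m_left else m_right
      lab <- lab + 1L
      if (any(labels[m] != 0L))
        stop("grid too small: region '", nm, "_", side,
             "' overlaps an already placed region")
      labels[m] <- lab
      name_vec[paste0(nm, "_", side)] <- lab
    }
  }
  structure(list(labels = volume(labels, voxel_size_mm, space_tag),
                 names = name_vec,
                 grid_shape = n, voxel_size_mm = voxel_size_mm,
                 space_tag = space_tag),
            class = "svd_atlas")
}

#' @export
print.svd_atlas <- function(x, ...) {
  cat(sprintf("<svd_atlas> %s @ %g mm, %d regions\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              length(x$names)))
  invisible(x)
}

#' Spherical brain mask on the template grid
#'
#' The analysis brain mask used by the synthetic phantom: a centred sphere
#' covering 42 percent of the first grid dimension in radius.
#'
#' @inheritParams make_atlas
#' @return binary [volume()].
#' @export
make_brain_mask <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 2,
                            space_tag = "template") {
  n <- as.integer(grid_shape)
  cc <- (n + 1) / 2
  r <- 0.42 * n[1]
  d2 <- outer(outer((seq_len(n[1]) - cc[1])^2, (seq_len(n[2]) - cc[2])^2, "+"),
              (seq_len(n[3]) - cc[3])^2, "+")
  volume((d2 <= r^2) * 1, voxel_size_mm, space_tag)
}

#' Resolve region-set names to atlas labels
#'
#' Accepts atomic region names (`"putamen_L"`), bilateral short names
#' (`"putamen"` = both sides), the composite `"striatum"` (putamen +
#' caudate, per side or bilateral), and `+`-joined unions
#' (`"striatum + hippocampus"`).
#'
#' @param atlas a `svd_atlas`.
#' @param regions character vector of region-set names.
#' @return integer vector of atlas labels.
#' @export
resolve_regions <- function(atlas, regions) {
  expand1 <- function(nm) {
    nm <- trimws(nm)
    if (grepl("+", nm, fixed = TRUE))
      return(unlist(lapply(strsplit(nm, "+", fixed = TRUE)[[1]], expand1)))
    if (nm %in% names(atlas$names)) return(atlas$names[[nm]])
    if (nm == "striatum") return(expand1("putamen + caudate"))
    if (nm %in% c("striatum_L", "striatum_R")) {
      side <- sub("striatum", "", nm)
      return(c(atlas$names[[paste0("putamen", side)]],
               atlas$names[[paste0("caudate", side)]]))
    }
    both <- paste0(nm, c("_L", "_R"))
    if (all(both %in% names(atlas$names)))
      return(unname(atlas$names[both]))
    stop("unknown region name: '", nm, "'")
  }
  sort(unique(unlist(lapply(regions, expand1))))
}

#' Binary mask for a region set
#'
#' @inheritParams resolve_regions
#' @return binary [volume()] covering the union of the named regions.
#' @export
roi_mask <- function(atlas, regions) {
  labs <- resolve_regions(atlas, regions)
  lab_arr <- vol_data(atlas$labels)
  m <- array(as.numeric(lab_arr %in% labs), dim = dim(lab_arr))
  volume(m, atlas$voxel_size_mm, atlas$space_tag)
}
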