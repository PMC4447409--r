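#' Ellipsoid specification for phantom geometry
#'
#' @param class tissue class name (see [tissue_classes()]).
#' @param center numeric length-3 voxel coordinates (1-based).
#' @param radii numeric length-3 semi-axes in voxels, all > 0.
#' @return A list of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(class, center, radii) {
  if (!class %in% names(tissue_classes()))
    stop("unknown tissue class: ", class)
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  structure(list(class = class, center = as.numeric(center),
                 radii = as.numeric(radii)), class = "ellipsoid_spec")
}

#' Default phantom geometry
#'
#' Four non-overlapping ellipsoids (semi-axes 4 x 4 x 2.5 voxels, ~150 voxels
#' each) in a 32 x 32 x 16 grid. The real tumors averaged ~2 cm with a ~1 cm
#' ablation zone; at a nominal ~1.2 mm isotropic voxel these ellipsoids have
#' the right order of magnitude while keeping fits fast.
#'
#' @param shape integer length-3 grid dimensions (centers scale with it).
#' @param radii semi-axes in voxels shared by the four ellipsoids.
#' @return List of [ellipsoid_spec()] objects, one per class.
#' @export
default_geometry <- function(shape = c(32L, 32L, 16L), radii = c(4, 4, 2.5)) {
  at <- function(fx, fy, fz)
    pmin(pmax(round(c(fx, fy, fz) * shape), ceiling(1 + radii)),
         floor(shape - radii))
  list(
    ellipsoid_spec("T_RFA",      at(0.28, 0.28, 0.31), radii),
    ellipsoid_spec("T_RESIDUAL", at(0.75, 0.28, 0.31), radii),
    ellipsoid_spec("T_CONTROL",  at(0.28, 0.75, 0.69), radii),
    ellipsoid_spec("NORMAL",     at(0.75, 0.75, 0.69), radii)
  )
}

#' Build an integer label volume from ellipsoid geometry
#'
#' Voxels whose centers fall inside an ellipsoid get that class's mask code;
#' all other voxels are 0. Ellipsoids must lie fully inside the grid and must
#' not overlap.
#'
#' @param shape integer length-3 grid dimensions, all positive.
#' @param geometry list of [ellipsoid_spec()]; may be empty.
#' @return 3D integer array of labels.
#' @export
#' @examples
#' labs <- make_label_volume(c(20, 20, 10),
#'   list(ellipsoid_spec("T_RFA", c(10, 10, 5), c(3, 3, 2))))
#' table(labs)
make_label_volume <- function(shape, geometry = list()) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1))
    stop("shape must be three positive integers")
  labels <- array(0L, dim = shape)
  if (length(geometry) == 0) return(labels)
  codes <- tissue_classes()
  ax <- seq_len(shape[1]); ay <- seq_len(shape[2]); az <- seq_len(shape[3])
  for (e in geometry) {
    if (!inherits(e, "ellipsoid_spec")) stop("geometry entries must be ellipsoid_spec")
    if (any(e$center - e$radii < 1) || any(e$center + e$radii > shape))
      stop("geometry error: ellipsoid for ", e$class, " extends outside the grid")
    dx2 <- ((ax - e$center[1]) / e$radii[1])^2
    dy2 <- ((ay - e$center[2]) / e$radii[2])^2
    dz2 <- ((az - e$center[3]) / e$radii[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    if (any(labels[inside] != 0L))
      stop("geometry error: ellipsoid for ", e$class,
           " overlaps a previously placed region")
    labels[inside] <- codes[[e$class]]
  }
  labels
}
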