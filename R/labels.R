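#' Cortical labels (surface vertex sets and/or voxel masks)
#'
#' A cortical label names a region (e.g. V1, V2) either as a set of vertex
#' indices on a surface mesh, as a voxel mask on a regular grid with a
#' voxel-to-world affine, or both.  Surface labels are authoritative for
#' retinotopy projection; voxel labels are the ones subject to overlap
#' resolution, mirroring the way interpolation into diffusion volume space
#' introduces overlaps at areal borders.
#'
#' @param name label name.
#' @param vertices integer vertex indices (1-based), or `NULL`.
#' @param voxels integer linear voxel indices (1-based into `dim`), or `NULL`.
#' @param dim integer grid dimensions (length 3), required with `voxels`.
#' @param affine 4 x 4 voxel-to-world matrix mapping 0-based voxel indices
#'   to world mm (RAS), required with `voxels`.
#' @return a `"cortical_label"` object.
#' @export
cortical_label <- function(name, vertices = NULL, voxels = NULL,
                           dim = NULL, affine = NULL) {
  if (is.null(vertices) && is.null(voxels)) {
    abort("a cortical label needs vertices and/or voxels")
  }
  if (!is.null(vertices)) {
    vertices <- as.integer(vertices)
    if (anyDuplicated(vertices)) abort("duplicate vertex indices in label")
    if (any(vertices < 1L)) abort("vertex indices must be positive")
    vertices <- sort(vertices)
  }
  if (!is.null(voxels)) {
    if (is.null(dim) || is.null(affine)) {
      abort("voxel labels need grid dimensions and a voxel-to-world affine")
    }
    dim <- as.integer(dim)
    stopifnot(length(dim) == 3, all(dim(as.matrix(affine)) == c(4, 4)))
    voxels <- as.integer(voxels)
    if (anyDuplicated(voxels)) abort("duplicate voxel indices in label")
    if (any(voxels < 1L) || any(voxels > prod(dim))) abort("voxel indices out of range")
    voxels <- sort(voxels)
  }
  structure(list(name = name, vertices = vertices, voxels = voxels,
                 dim = dim, affine = if (is.null(affine)) NULL else as.matrix(affine)),
            class = "cortical_label")
}

#' @export
print.cortical_label <- function(x, ...) {
  cat(sprintf("<cortical_label %s> %s%s\n", x$name,
              if (!is.null(x$vertices)) sprintf("%d vertices ", length(x$vertices)) else "",
              if (!is.null(x$voxels)) sprintf("%d voxels on %s grid",
                                              length(x$voxels), paste(x$dim, collapse = "x")) else ""))
  invisible(x)
}

#' Read / write voxel label masks as NIfTI
#'
#' Nonzero voxels become the label; the NIfTI sform/qform supplies the
#' voxel-to-world affine.
#'
#' @param path NIfTI file path.
#' @param name label name.
#' @return `read_label_nifti()` returns a voxel-based [cortical_label()].
#' @export
read_label_nifti <- function(path, name) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) abort("label mask must be a 3D volume")
  aff <- structure(RNifti::xform(img), class = NULL)
  cortical_label(name, voxels = which(arr != 0), dim = dim(arr), affine = aff)
}

#' @rdname read_label_nifti
#' @param label a voxel-based [cortical_label()].
#' @export
write_label_nifti <- function(label, path) {
  if (is.null(label$voxels)) abort("label has no voxel representation")
  arr <- array(0L, dim = label$dim)
  arr[label$voxels] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(label$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world mm -> 0-based voxel indices (continuous)
world_to_voxel <- function(points, affine) {
  pts <- as_points3(points, "points")
  inv <- solve(affine)
  h <- cbind(pts, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' Point membership in a cortical label
#'
#' Voxel labels: world points are mapped through the inverse affine and
#' rounded to the nearest voxel (half-open voxel boxes).  Surface labels:
#' a point belongs to the label when its nearest labelled vertex is within
#' `tol` mm.
#'
#' @param label a [cortical_label()].
#' @param points n x 3 world coordinates (mm).
#' @param mesh the [surface_mesh()] carrying vertex labels (surface labels
#'   only).
#' @param tol nearest-vertex tolerance in mm for surface labels.
#' @return logical vector, one entry per point.
#' @export
label_contains <- function(label, points, mesh = NULL, tol = 2) {
  pts <- as_points3(points, "points")
  if (!is.null(label$voxels)) {
    ijk <- round(world_to_voxel(pts, label$affine))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < label$dim[1] &
          ijk[, 2] >= 0 & ijk[, 2] < label$dim[2] &
          ijk[, 3] >= 0 & ijk[, 3] < label$dim[3]
    lin <- rep(NA_integer_, nrow(pts))
    lin[ok] <- 1L + ijk[ok, 1] + label$dim[1] * (ijk[ok, 2] + label$dim[2] * ijk[ok, 3])
    !is.na(lin) & lin %in% label$voxels
  } else {
    if (is.null(mesh)) abort("surface labels need the carrying mesh")
    lv <- mesh$vertices[label$vertices, , drop = FALSE]
    vapply(seq_len(nrow(pts)), function(i) {
      min(sqrt(colSums((t(lv) - pts[i, ])^2))) <= tol
    }, logical(1))
  }
}

#' Resolve V1/V2 voxel-label overlap with a probability map
#'
#' Registration of surface-drawn labels into volume space can make V1 and
#' V2 overlap at the areal border.  Each overlap voxel is reassigned to V1
#' when its V1 probability is at least 0.5 (ties go to V1 and are
#' reported), otherwise to V2.  The outputs are disjoint and conserve the
#' union of the inputs.
#'
#' @param v1,v2 voxel-based [cortical_label()]s on a common grid.
#' @param prob numeric array (grid-shaped) or vector of per-voxel V1
#'   probabilities; must be defined (non-`NA`) on every overlap voxel.
#' @return list with elements `v1` and `v2`, disjoint labels.
#' @export
resolve_label_overlap <- function(v1, v2, prob) {
  if (is.null(v1$voxels) || is.null(v2$voxels)) {
    abort("overlap resolution operates on voxel-based labels")
  }
  if (!identical(v1$dim, v2$dim)) abort("labels are not on a common voxel grid")
  overlap <- intersect(v1$voxels, v2$voxels)
  if (length(overlap) == 0) return(list(v1 = v1, v2 = v2))
  p <- as.vector(prob)[overlap]
  if (anyNA(p)) {
    abort(sprintf("probability undefined at overlap voxel(s): %s",
                  paste(head(overlap[is.na(p)], 10), collapse = ", ")))
  }
  to_v1 <- overlap[p >= 0.5]
  to_v2 <- overlap[p < 0.5]
  ties <- overlap[p == 0.5]
  if (length(ties)) {
    inform(sprintf("%d overlap voxel(s) at probability 0.5 assigned to %s",
                   length(ties), v1$name))
  }
  out1 <- cortical_label(v1$name, vertices = v1$vertices,
                         voxels = union(setdiff(v1$voxels, to_v2), to_v1),
                         dim = v1$dim, affine = v1$affine)
  out2 <- cortical_label(v2$name, vertices = v2$vertices,
                         voxels = union(setdiff(v2$voxels, to_v1), to_v2),
                         dim = v2$dim, affine = v2$affine)
  list(v1 = out1, v2 = out2)
}
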