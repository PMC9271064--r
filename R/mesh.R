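# Image convention used throughout the package: a 2D image is a numeric matrix
# with dim = c(nx, ny); pixel (i, j) (1-based) is voxel-centered at physical
# coordinates ((i-1)*sx, (j-1)*sy) mm.

#' Physical coordinates of pixel centers
#'
#' @param dim integer length-2, grid shape.
#' @param spacing numeric length-2, mm per pixel (x, y).
#' @return list with vectors `x`, `y` (mm) and matrices `X`, `Y`.
#' @keywords internal
pixel_coords <- function(dim, spacing) {
  x <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  list(x = x, y = y,
       X = matrix(x, dim[1], dim[2]),
       Y = matrix(y, dim[1], dim[2], byrow = TRUE))
}

#' Build a triangular finite-element mesh over a pixel mask
#'
#' Lays a regular node grid over the bounding box of `domain_mask` and splits
#' each retained quad cell into two right triangles. A quad is retained when at
#' least half of the pixel centers it covers are inside the mask, which keeps
#' the meshed area an unbiased estimate of the rasterized domain area. The node
#' spacing is chosen so that the mean edge length (two legs and one diagonal
#' per quad) equals `target_edge_mm`; the minimum triangle angle is 45 degrees
#' by construction.
#'
#' @param domain_mask logical matrix, the region to mesh.
#' @param spacing numeric length-2, mm per pixel.
#' @param target_edge_mm target mean edge length in mm (default 1.5).
#' @param roi_mask optional logical matrix flagging tumor pixels; used to set
#'   `node_in_roi` and element ROI membership.
#' @return an object of class `tri_mesh`: nodes (n x 2, mm), triangles
#'   (m x 3, counter-clockwise), element areas and shape-function gradients,
#'   boundary node indices, and ROI flags.
#' @export
build_mesh <- function(domain_mask, spacing, target_edge_mm = 1.5, roi_mask = NULL) {
  stopifnot(is.matrix(domain_mask), all(spacing > 0), target_edge_mm > 0)
  mode(domain_mask) <- "logical"
  if (sum(domain_mask) < 4L)
    stop("domain_mask too small to mesh at the requested edge length")
  # mean edge of the right-triangle tiling is (2*h + sqrt(2)*h)/3 = 1.1381 h
  h <- target_edge_mm / ((2 + sqrt(2)) / 3)
  pc <- pixel_coords(dim(domain_mask), spacing)
  idx <- which(domain_mask, arr.ind = TRUE)
  x0 <- min(pc$x[idx[, 1]]) - spacing[1] / 2
  x1 <- max(pc$x[idx[, 1]]) + spacing[1] / 2
  y0 <- min(pc$y[idx[, 2]]) - spacing[2] / 2
  y1 <- max(pc$y[idx[, 2]]) + spacing[2] / 2
  nqx <- max(1L, ceiling((x1 - x0) / h))
  nqy <- max(1L, ceiling((y1 - y0) / h))
  gx <- seq(x0, x1, length.out = nqx + 1L)
  gy <- seq(y0, y1, length.out = nqy + 1L)

  # fraction of pixel centers inside each quad that are in the mask
  px_qx <- findInterval(pc$x, gx, rightmost.closed = TRUE)
  px_qy <- findInterval(pc$y, gy, rightmost.closed = TRUE)
  inside <- px_qx >= 1 & px_qx <= nqx
  insidey <- px_qy >= 1 & px_qy <= nqy
  qi <- rep(px_qx, times = length(pc$y))
  qj <- rep(px_qy, each = length(pc$x))
  ok <- rep(inside, times = length(pc$y)) & rep(insidey, each = length(pc$x))
  cell <- (qj - 1L) * nqx + qi
  tot <- tabulate(cell[ok], nbins = nqx * nqy)
  hit <- tabulate(cell[ok & as.vector(domain_mask)], nbins = nqx * nqy)
  keep <- tot > 0 & hit / pmax(tot, 1L) >= 0.5
  # quads finer than a pixel may contain no pixel center: use the mask value
  # nearest the quad center instead
  if (any(tot == 0L)) {
    qcx <- (gx[-length(gx)] + gx[-1]) / 2
    qcy <- (gy[-length(gy)] + gy[-1]) / 2
    ctr <- cbind(rep(qcx, times = nqy), rep(qcy, each = nqx))
    empty <- tot == 0L
    keep[empty] <- mask_at_points(domain_mask, spacing, ctr[empty, , drop = FALSE])
  }
  if (!any(keep))
    stop("domain_mask too small to mesh at the requested edge length")

  keep_q <- which(keep)
  qx <- (keep_q - 1L) %% nqx + 1L
  qy <- (keep_q - 1L) %/% nqx + 1L
  # node ids on the (nqx+1) x (nqy+1) grid
  nid <- function(i, j) (j - 1L) * (nqx + 1L) + i
  n1 <- nid(qx, qy); n2 <- nid(qx + 1L, qy)
  n3 <- nid(qx + 1L, qy + 1L); n4 <- nid(qx, qy + 1L)
  # two CCW triangles per quad: (n1,n2,n3) and (n1,n3,n4)
  tris <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  used <- sort(unique(as.vector(tris)))
  remap <- integer((nqx + 1L) * (nqy + 1L))
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3)
  ui <- (used - 1L) %% (nqx + 1L) + 1L
  uj <- (used - 1L) %/% (nqx + 1L) + 1L
  nodes <- cbind(x = gx[ui], y = gy[uj])

  geom <- tri_geometry(nodes, tris)
  if (any(geom$area <= 0)) stop("degenerate triangle produced")

  # boundary edges appear in exactly one triangle
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ekey)
  bnd <- names(tab)[tab == 1L]
  bnodes <- sort(unique(as.integer(unlist(strsplit(bnd, " ")))))

  mesh <- structure(list(
    nodes = nodes, triangles = tris, areas = geom$area,
    grad_b = geom$b, grad_c = geom$c,
    centroids = geom$centroid,
    boundary_nodes = bnodes,
    spacing = spacing, h = h, target_edge_mm = target_edge_mm,
    cache = new.env(parent = emptyenv())
  ), class = "tri_mesh")
  mesh$node_in_roi <- if (is.null(roi_mask)) rep(FALSE, nrow(nodes)) else
    mask_at_points(roi_mask, spacing, nodes)
  mesh$elem_in_roi <- if (is.null(roi_mask)) rep(FALSE, nrow(tris)) else
    mask_at_points(roi_mask, spacing, mesh$centroids)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d nodes, %d triangles, mean edge %.3f mm, %d ROI elements\n",
              nrow(x$nodes), nrow(x$triangles), mean(edge_lengths(x)),
              sum(x$elem_in_roi)))
  invisible(x)
}

# P1 triangle geometry: areas, shape-function gradient coefficients, centroids.
# For triangle (1,2,3): grad(phi_i) = (b_i, c_i) with
# b_i = (y_j - y_k)/(2A), c_i = (x_k - x_j)/(2A).
tri_geometry <- function(nodes, tris) {
  x1 <- nodes[tris[, 1], 1]; y1 <- nodes[tris[, 1], 2]
  x2 <- nodes[tris[, 2], 1]; y2 <- nodes[tris[, 2], 2]
  x3 <- nodes[tris[, 3], 1]; y3 <- nodes[tris[, 3], 2]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  A <- area2 / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / area2
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / area2
  list(area = A, b = b, c = cc,
       centroid = cbind((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3))
}

edge_lengths <- function(mesh) {
  tris <- mesh$triangles; nodes <- mesh$nodes
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(ekey), , drop = FALSE]
  sqrt(rowSums((nodes[e[, 1], , drop = FALSE] - nodes[e[, 2], , drop = FALSE])^2))
}

min_triangle_angle <- function(mesh) {
  tris <- mesh$triangles; nodes <- mesh$nodes
  ang <- function(a, b, c) {
    u <- nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE]
    v <- nodes[c, , drop = FALSE] - nodes[a, , drop = FALSE]
    acos(pmin(1, pmax(-1, rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2))))))
  }
  th <- cbind(ang(tris[, 1], tris[, 2], tris[, 3]),
              ang(tris[, 2], tris[, 3], tris[, 1]),
              ang(tris[, 3], tris[, 1], tris[, 2]))
  min(th) * 180 / pi
}

# nearest-pixel mask lookup at physical points (n x 2)
mask_at_points <- function(mask, spacing, pts) {
  i <- pmin(pmax(round(pts[, 1] / spacing[1]) + 1L, 1L), nrow(mask))
  j <- pmin(pmax(round(pts[, 2] / spacing[2]) + 1L, 1L), ncol(mask))
  mask[cbind(i, j)]
}

#' Meshing domain around a tumor
#'
#' The modeled domain is the tumor ROI dilated by `margin_mm` of host tissue,
#' clipped to the breast mask, so that the mechanical model has surrounding
#' tissue to push against.
#'
#' @param roi_mask logical matrix, tumor ROI (may be the union over time points).
#' @param breast_mask logical matrix, tissue domain.
#' @param spacing mm per pixel.
#' @param margin_mm dilation margin (default 10 mm).
#' @return logical matrix.
#' @export
mesh_domain_mask <- function(roi_mask, breast_mask, spacing, margin_mm = 10) {
  stopifnot(all(dim(roi_mask) == dim(breast_mask)))
  dilate_mask(roi_mask, spacing, margin_mm) & breast_mask
}

#' Dilate a pixel mask by a physical margin
#'
#' Brute-force distance transform against the mask pixels; exact and fast
#' enough for the single-slice grids this package works on.
#'
#' @param mask logical matrix.
#' @param spacing mm per pixel.
#' @param margin_mm dilation radius in mm.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, spacing, margin_mm) {
  pc <- pixel_coords(dim(mask), spacing)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  rx <- pc$x[idx[, 1]]; ry <- pc$y[idx[, 2]]
  d2 <- matrix(Inf, nrow(mask), ncol(mask))
  for (k in seq_along(rx)) {
    dk <- (pc$X - rx[k])^2 + (pc$Y - ry[k])^2
    d2 <- pmin(d2, dk)
  }
  d2 <= margin_mm^2
}

#' Partition tumor elements into regions by k-means on centroids
#'
#' Tumor elements are clustered on their centroid (x, y) coordinates into
#' `round(n_elements / elements_per_region)` regions (at least 1), giving the
#' piecewise-constant support for regional proliferation-rate reconstruction.
#'
#' @param mesh a `tri_mesh`.
#' @param roi_elements integer indices of tumor elements (defaults to
#'   `which(mesh$elem_in_roi)`).
#' @param elements_per_region target mean elements per region (default 5).
#' @param seed RNG seed for k-means restarts (default 0).
#' @return object of class `region_partition`: `region_of_element` (named by
#'   element index), `n_regions`, `region_areas` (mm^2), `elements`.
#' @export
partition_regions <- function(mesh, roi_elements = NULL, elements_per_region = 5,
                              seed = 0L) {
  if (is.null(roi_elements)) roi_elements <- which(mesh$elem_in_roi)
  stopifnot(length(roi_elements) > 0, elements_per_region >= 1)
  n_reg <- max(1L, round(length(roi_elements) / elements_per_region))
  cen <- mesh$centroids[roi_elements, , drop = FALSE]
  n_reg <- min(n_reg, nrow(unique(cen)))
  if (n_reg == 1L) {
    lab <- rep(1L, length(roi_elements))
  } else {
    lab <- with_preserved_seed(seed, {
      stats::kmeans(cen, centers = n_reg, nstart = 10L, iter.max = 100L)$cluster
    })
  }
  areas <- as.vector(tapply(mesh$areas[roi_elements], lab, sum))
  structure(list(
    region_of_element = stats::setNames(as.integer(lab), roi_elements),
    elements = roi_elements,
    n_regions = n_reg,
    region_areas = areas
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %d regions over %d elements (mean area %.2f mm^2)\n",
              x$n_regions, length(x$elements), mean(x$region_areas)))
  invisible(x)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample an image at mesh nodes (bilinear)
#'
#' @param image numeric matrix in the package's voxel-centered frame.
#' @param mesh a `tri_mesh` sharing the physical frame.
#' @param spacing mm per pixel of `image` (defaults to the mesh spacing).
#' @return numeric vector, one value per node. Exact for bilinear (hence
#'   linear) images.
#' @export
raster_to_nodal <- function(image, mesh, spacing = mesh$spacing) {
  pts <- mesh$nodes
  fx <- pts[, 1] / spacing[1]
  fy <- pts[, 2] / spacing[2]
  eps <- 1e-9
  fx <- pmin(pmax(fx, 0), nrow(image) - 1 - eps * 0)
  fy <- pmin(pmax(fy, 0), ncol(image) - 1 - eps * 0)
  if (any(pts[, 1] / spacing[1] < -1e-6 | pts[, 1] / spacing[1] > nrow(image) - 1 + 1e-6 |
          pts[, 2] / spacing[2] < -1e-6 | pts[, 2] / spacing[2] > ncol(image) - 1 + 1e-6))
    stop("mesh node outside image frame")
  i0 <- pmin(floor(fx), nrow(image) - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), ncol(image) - 2); j0 <- pmax(j0, 0)
  tx <- fx - i0; ty <- fy - j0
  v00 <- image[cbind(i0 + 1, j0 + 1)]
  v10 <- image[cbind(i0 + 2, j0 + 1)]
  v01 <- image[cbind(i0 + 1, j0 + 2)]
  v11 <- image[cbind(i0 + 2, j0 + 2)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Rasterize a nodal field back onto a pixel grid (barycentric)
#'
#' Pixels whose centers fall outside the mesh receive `fill`.
#'
#' @param field numeric vector, one value per mesh node.
#' @param mesh a `tri_mesh`.
#' @param grid_dim integer length-2 output shape.
#' @param spacing mm per pixel (defaults to mesh spacing).
#' @param fill value for uncovered pixels (default `NA`).
#' @return numeric matrix. Exact for fields linear in (x, y).
#' @export
nodal_to_raster <- function(field, mesh, grid_dim, spacing = mesh$spacing,
                            fill = NA_real_) {
  stopifnot(length(field) == nrow(mesh$nodes))
  out <- matrix(fill, grid_dim[1], grid_dim[2])
  pc <- pixel_coords(grid_dim, spacing)
  tris <- mesh$triangles; nodes <- mesh$nodes
  tol <- 1e-9
  for (t in seq_len(nrow(tris))) {
    p1 <- nodes[tris[t, 1], ]; p2 <- nodes[tris[t, 2], ]; p3 <- nodes[tris[t, 3], ]
    xi <- which(pc$x >= min(p1[1], p2[1], p3[1]) - tol &
                pc$x <= max(p1[1], p2[1], p3[1]) + tol)
    yi <- which(pc$y >= min(p1[2], p2[2], p3[2]) - tol &
                pc$y <= max(p1[2], p2[2], p3[2]) + tol)
    if (!length(xi) || !length(yi)) next
    X <- rep(pc$x[xi], times = length(yi))
    Y <- rep(pc$y[yi], each = length(xi))
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    l2 <- ((X - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (Y - p1[2])) / det
    l3 <- ((p2[1] - p1[1]) * (Y - p1[2]) - (X - p1[1]) * (p2[2] - p1[2])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (!any(inside)) next
    vals <- l1 * field[tris[t, 1]] + l2 * field[tris[t, 2]] + l3 * field[tris[t, 3]]
    ii <- rep(xi, times = length(yi))[inside]
    jj <- rep(yi, each = length(xi))[inside]
    out[cbind(ii, jj)] <- vals[inside]
  }
  out
}

# node x element incidence weighted by area/3, row-normalized by total
# adjacent area: maps an element field to a consistent nodal field and its
# transpose chains gradients back to elements.
node_element_weights <- function(mesh) {
  if (!is.null(mesh$cache) && !is.null(mesh$cache$Pn)) return(mesh$cache$Pn)
  Pn <- node_element_weights_impl(mesh)
  if (!is.null(mesh$cache)) mesh$cache$Pn <- Pn
  Pn
}

node_element_weights_impl <- function(mesh) {
  tris <- mesh$triangles
  i <- as.vector(tris)
  j <- rep(seq_len(nrow(tris)), times = 3)
  w <- rep(mesh$areas / 3, times = 3)
  P <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(nrow(mesh$nodes), nrow(tris)))
  rs <- Matrix::rowSums(P)
  Matrix::Diagonal(x = 1 / rs) %*% P
}
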