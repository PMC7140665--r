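#' Spatiotemporal connected components of a binary stack
#'
#' Groups supra-threshold voxels into maximal components connected in the
#' (x, y, t) volume. Connectivity is 26 (all voxels sharing a face, edge
#' or corner) by default, or 6 (faces only). Components are labeled
#' deterministically by the lexicographic (t, y, x) order of their first
#' voxel.
#'
#' @param binary a `binary_stack` (or plain 0/1 array).
#' @param connectivity 26 or 6.
#' @return a `ca_cluster_set`: list of `ca_cluster` objects, each with
#'   `id`, `voxels` (matrix with columns x, y, t; 1-based), `volume`,
#'   `duration`, `max_surface`, `origin` (x, y centroid of first-frame
#'   pixels, rounded).
#' @export
find_clusters <- function(binary, connectivity = 26L) {
  b <- if (inherits(binary, "binary_stack")) binary$voxels else binary
  stopifnot(length(dim(b)) == 3L, connectivity %in% c(6L, 26L))
  d <- dim(b)
  pos <- which(b == 1)
  if (length(pos) == 0L)
    return(structure(list(), class = "ca_cluster_set"))
  rank <- array(0L, d)
  rank[pos] <- seq_along(pos)
  coord <- arrayInd(pos, d)  # columns: y, x, t
  offsets <- if (connectivity == 6L) {
    matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1), ncol = 3, byrow = TRUE)
  } else {
    g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dt = -1:1))
    # lexicographically positive half of the 26-neighborhood
    g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
      drop = FALSE]
  }
  edges <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    off <- offsets[i, ]
    ny <- coord[, 1] + off[1]; nx <- coord[, 2] + off[2]
    nt <- coord[, 3] + off[3]
    ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nt >= 1 & nt <= d[3]
    if (!any(ok)) next
    nb <- rank[cbind(ny[ok], nx[ok], nt[ok])]
    hit <- nb > 0L
    if (any(hit))
      edges[[i]] <- cbind(which(ok)[hit], nb[hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    if (is.null(el)) matrix(integer(0), 0, 2) else el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(pos) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  clusters <- lapply(split(seq_along(pos), memb), function(ix) {
    vox <- coord[ix, , drop = FALSE]
    new_ca_cluster(vox)
  })
  # deterministic ordering by first voxel (t, y, x)
  first <- t(vapply(clusters, function(cl) cl$first_voxel, numeric(3)))
  ord <- order(first[, 1], first[, 2], first[, 3])
  clusters <- unname(clusters[ord])
  for (i in seq_along(clusters)) clusters[[i]]$id <- i
  structure(clusters, class = "ca_cluster_set")
}

# vox: matrix with columns (y, x, t), 1-based
new_ca_cluster <- function(vox) {
  o <- order(vox[, 3], vox[, 1], vox[, 2])
  vox <- vox[o, , drop = FALSE]
  t_min <- vox[1, 3]
  first_px <- vox[vox[, 3] == t_min, , drop = FALSE]
  origin <- c(x = round(mean(first_px[, 2])), y = round(mean(first_px[, 1])))
  structure(list(
    id = NA_integer_,
    voxels = cbind(x = vox[, 2], y = vox[, 1], t = vox[, 3]),
    volume = nrow(vox),
    duration = max(vox[, 3]) - t_min + 1L,
    max_surface = max(tabulate(vox[, 3] - t_min + 1L)),
    origin = origin,
    first_voxel = c(t = vox[1, 3], y = vox[1, 1], x = vox[1, 2])),
    class = "ca_cluster")
}

#' @export
print.ca_cluster <- function(x, ...) {
  cat(sprintf("<ca_cluster %s> volume %d, duration %d, max surface %d, origin (%d, %d)\n",
              x$id, x$volume, x$duration, x$max_surface,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
print.ca_cluster_set <- function(x, ...) {
  cat(sprintf("<ca_cluster_set> %d cluster(s)\n", length(x)))
  invisible(x)
}

#' Metrics of a single calcium cluster
#'
#' @param cluster a `ca_cluster`.
#' @param pixel_size optional pixel size (micrometers) to also report the
#'   maximum surface in square micrometers.
#' @return list with `volume` (voxels), `duration` (frames),
#'   `max_surface` (pixels), `origin` (x, y), and `max_surface_um2` when
#'   `pixel_size` is given.
#' @export
cluster_metrics <- function(cluster, pixel_size = NULL) {
  stopifnot(inherits(cluster, "ca_cluster"))
  out <- list(volume = cluster$volume, duration = cluster$duration,
              max_surface = cluster$max_surface, origin = cluster$origin)
  if (!is.null(pixel_size))
    out$max_surface_um2 <- cluster$max_surface * pixel_size^2
  out
}

#' Cluster set as a flat table
#'
#' @param clusters a `ca_cluster_set`.
#' @param zero_based export pixel/frame indices 0-based (default TRUE, the
#'   convention of all exported tables).
#' @return data.frame with id, volume, duration, max_surface, origin_x,
#'   origin_y, t_start.
#' @export
cluster_table <- function(clusters, zero_based = TRUE) {
  z <- if (zero_based) 1L else 0L
  if (length(clusters) == 0L)
    return(data.frame(id = integer(0), volume = integer(0),
                      duration = integer(0), max_surface = integer(0),
                      origin_x = integer(0), origin_y = integer(0),
                      t_start = integer(0)))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(id = cl$id, volume = cl$volume, duration = cl$duration,
               max_surface = cl$max_surface,
               origin_x = cl$origin[1] - z, origin_y = cl$origin[2] - z,
               t_start = cl$first_voxel[1] - z, row.names = NULL)
  }))
}

#' Anatomical classification of large calcium domains
#'
#' Clusters strictly larger than `min_volume` voxels are assigned to the
#' atlas region containing their spatial origin; counts are normalized to
#' the total number of classified domains in the recording.
#'
#' @param clusters a `ca_cluster_set`.
#' @param atlas a `region_atlas` on the same grid.
#' @param min_volume strict volume threshold (default 300 voxels).
#' @return data.frame with region, count, fraction ("outside" collects
#'   origins at label 0 or beyond the atlas).
#' @export
classify_by_region <- function(clusters, atlas, min_volume = 300L) {
  stopifnot(inherits(atlas, "region_atlas"))
  big <- Filter(function(cl) cl$volume > min_volume, clusters)
  region_names <- c(names(atlas$names), "outside")
  counts <- stats::setNames(integer(length(region_names)), region_names)
  for (cl in big) {
    x <- cl$origin["x"]; y <- cl$origin["y"]
    lab <- if (y >= 1 && y <= nrow(atlas$labels) &&
               x >= 1 && x <= ncol(atlas$labels))
      atlas$labels[y, x] else 0L
    nm <- if (lab == 0L) "outside" else
      names(atlas$names)[match(lab, atlas$names)]
    counts[nm] <- counts[nm] + 1L
  }
  total <- sum(counts)
  data.frame(region = region_names, count = as.integer(counts),
             fraction = if (total > 0) as.numeric(counts) / total else
               rep(NA_real_, length(counts)),
             row.names = NULL)
}

#' Total positive voxels per anatomical region
#'
#' @param binary a `binary_stack` (or 0/1 array).
#' @param atlas a `region_atlas` on the same grid.
#' @return data.frame with region and voxel count (plus "outside").
#' @export
region_activity <- function(binary, atlas) {
  b <- if (inherits(binary, "binary_stack")) binary$voxels else binary
  stopifnot(inherits(atlas, "region_atlas"))
  d <- dim(b)
  if (d[1] != nrow(atlas$labels) || d[2] != ncol(atlas$labels))
    stop2("region_activity: atlas grid does not match the stack")
  per_pixel <- rowSums(matrix(b, d[1] * d[2], d[3]))
  lab <- as.vector(atlas$labels)
  region_names <- c(names(atlas$names), "outside")
  counts <- vapply(seq_along(region_names), function(i) {
    if (region_names[i] == "outside") sum(per_pixel[lab == 0L])
    else sum(per_pixel[lab == atlas$names[region_names[i]]])
  }, numeric(1))
  data.frame(region = region_names, voxels = as.integer(counts),
             row.names = NULL)
}
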