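#' Euclidean distances between parcel centroids
#'
#' Distance in mm between every pair of parcel centroids. This is the `r`
#' entering the exponential spatial kernel of the local order parameter and
#' the exponential distance rule of the structural connectome.
#'
#' @param centroids numeric matrix, one row per parcel, columns x/y/z in mm.
#' @return symmetric N x N matrix of distances in mm with zero diagonal.
#' @export
#' @examples
#' pairwise_distances(rbind(c(0, 0, 0), c(3, 4, 0)))
pairwise_distances <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (!all(is.finite(centroids))) {
    stop_invalid("centroid coordinates must be finite")
  }
  d <- as.matrix(stats::dist(centroids, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Synthetic brain-like parcel geometry
#'
#' Samples parcel centroids uniformly inside two mirrored hemisphere
#' ellipsoids (axis lengths 70 x 85 x 60 mm, centred at x = -40 and +40 mm),
#' so pairwise distances span roughly 3-150 mm, the range probed by the
#' spatial-scale grid of the turbulence measures. Each parcel gets a volume
#' (in voxel counts), a hemisphere flag, and one of the seven canonical
#' resting-state-network labels assigned by spatial k-means, which makes the
#' networks spatially contiguous like real RSNs.
#'
#' @param n_nodes number of parcels (>= 2).
#' @param seed integer seed; the geometry is deterministic given the seed.
#' @return an object of class `parcel_geometry`: a list with `centroids`
#'   (N x 3, mm), `distances` (N x N, mm), `rsn_labels` (factor with levels
#'   VIS, SM, DAT, VAT, LIM, CNT, DMN), `node_volumes` (voxel counts),
#'   `hemisphere` (factor L/R) and `n_nodes`.
#' @export
make_geometry <- function(n_nodes, seed = 1L) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2) {
    stop_invalid("n_nodes must be a single count >= 2")
  }
  n_nodes <- as.integer(n_nodes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  semi <- c(35, 42.5, 30)       # hemisphere ellipsoid semi-axes, mm
  offset <- 40                  # hemisphere centre offset on x, mm
  n_left <- n_nodes %/% 2L
  n_right <- n_nodes - n_left
  centroids <- rbind(
    sample_ellipsoid(n_left, semi) + matrix(c(-offset, 0, 0), n_left, 3, byrow = TRUE),
    sample_ellipsoid(n_right, semi) + matrix(c(offset, 0, 0), n_right, 3, byrow = TRUE)
  )
  hemisphere <- factor(ifelse(centroids[, 1] < 0, "L", "R"), levels = c("L", "R"))

  rsn_levels <- c("VIS", "SM", "DAT", "VAT", "LIM", "CNT", "DMN")
  # seven spatially contiguous networks; fewer when the parcellation is too
  # small for kmeans to separate them
  k <- max(1L, min(7L, n_nodes - 1L))
  cl <- stats::kmeans(centroids, centers = k, nstart = 5, iter.max = 50)$cluster
  rsn_labels <- factor(rsn_levels[cl], levels = rsn_levels)

  # parcel sizes in 2 mm voxels: the brain volume (two hemisphere
  # ellipsoids) tiled into n parcels, with right-skewed variability like
  # real parcellations (~150 voxels per parcel at the 1,000-parcel scale)
  brain_vol_mm3 <- 2 * (4 / 3) * pi * prod(semi)
  mean_voxels <- brain_vol_mm3 / (8 * n_nodes)
  node_volumes <- pmax(1L, as.integer(round(
    stats::rlnorm(n_nodes, log(mean_voxels) - 0.3^2 / 2, 0.3)
  )))

  structure(
    list(
      centroids = centroids,
      distances = pairwise_distances(centroids),
      rsn_labels = rsn_labels,
      node_volumes = node_volumes,
      hemisphere = hemisphere,
      n_nodes = n_nodes
    ),
    class = "parcel_geometry"
  )
}

# uniform sampling inside an origin-centred ellipsoid by rejection from the cube
sample_ellipsoid <- function(n, semi) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, n, 3)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 16L)
    u <- matrix(runif(3 * m, -1, 1), m, 3)
    keep <- rowSums(u^2) <= 1
    u <- u[keep, , drop = FALSE]
    take <- min(nrow(u), n - filled)
    if (take > 0) {
      out[(filled + 1):(filled + take), ] <- u[seq_len(take), , drop = FALSE] *
        matrix(semi, take, 3, byrow = TRUE)
      filled <- filled + take
    }
  }
  out
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat("<parcel_geometry> ", x$n_nodes, " parcels, max distance ",
      round(max(x$distances), 1), " mm\n", sep = "")
  invisible(x)
}

#' Tabular view of a parcel geometry
#'
#' @param x a `parcel_geometry`.
#' @param ... unused.
#' @return tibble with one row per parcel: node, x, y, z, volume, rsn, hemisphere.
#' @export
as_tibble.parcel_geometry <- function(x, ...) {
  geom <- x
  tibble::tibble(
    node = seq_len(geom$n_nodes),
    x = geom$centroids[, 1],
    y = geom$centroids[, 2],
    z = geom$centroids[, 3],
    volume = geom$node_volumes,
    rsn = as.character(geom$rsn_labels),
    hemisphere = as.character(geom$hemisphere)
  )
}

#' Write / read a parcel geometry as a delimited table
#'
#' @param geometry a `parcel_geometry`.
#' @param path file path for a tab-separated table.
#' @return `read_geometry` returns a `parcel_geometry` rebuilt from the table.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.table(as.data.frame(tibble::as_tibble(geometry)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  centroids <- as.matrix(tab[, c("x", "y", "z")])
  dimnames(centroids) <- NULL
  structure(
    list(
      centroids = centroids,
      distances = pairwise_distances(centroids),
      rsn_labels = factor(tab$rsn, levels = c("VIS", "SM", "DAT", "VAT", "LIM", "CNT", "DMN")),
      node_volumes = tab$volume,
      hemisphere = factor(tab$hemisphere, levels = c("L", "R")),
      n_nodes = nrow(tab)
    ),
    class = "parcel_geometry"
  )
}

# save/restore the global RNG state so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
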