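#' Lesion-node overlap table
#'
#' Container for the fraction of each parcel's volume covered by each
#' patient's lesion, the quantity that drives the simulated attack.
#'
#' @param overlap numeric patients x nodes matrix of fractions in \[0, 1\].
#' @param node_volumes per-node volumes (voxel counts).
#' @param patient_ids optional patient identifiers.
#' @return object of class `lesion_overlap`.
#' @export
lesion_overlap <- function(overlap, node_volumes = NULL, patient_ids = NULL) {
  overlap <- as.matrix(overlap)
  if (anyNA(overlap) || any(overlap < 0) || any(overlap > 1)) {
    stop_invalid("overlap fractions must be finite and in [0, 1]")
  }
  if (is.null(patient_ids)) patient_ids <- paste0("patient_", seq_len(nrow(overlap)))
  structure(
    list(overlap = overlap, node_volumes = node_volumes, patient_ids = patient_ids),
    class = "lesion_overlap"
  )
}

#' @export
print.lesion_overlap <- function(x, ...) {
  cat("<lesion_overlap> ", nrow(x$overlap), " patients x ", ncol(x$overlap),
      " nodes, ", sum(x$overlap > 0), " positive entries\n", sep = "")
  invisible(x)
}

#' @rdname lesion_overlap
#' @param x a `lesion_overlap`.
#' @param ... unused.
#' @export
tidy.lesion_overlap <- function(x, ...) {
  tibble::tibble(
    patient = rep(x$patient_ids, times = ncol(x$overlap)),
    node = rep(seq_len(ncol(x$overlap)), each = nrow(x$overlap)),
    overlap = as.vector(x$overlap)
  )
}

#' Synthetic focal-lesion cohort
#'
#' Gives each synthetic patient a set of spherical lesion foci (centres
#' drawn at parcel centroids so lesions lie inside the brain) and computes
#' each parcel's lesioned volume fraction analytically, approximating the
#' parcel as a sphere of equal volume around its centroid (2 mm voxels).
#' Fractions from multiple foci add and are clipped to \[0, 1\].
#'
#' @param geometry a `parcel_geometry`.
#' @param n_patients number of patients.
#' @param foci lesion foci per patient (default 3).
#' @param radius_mm lesion radius in mm (> 0; default 15, the cm scale of
#'   focal contusions in moderate-severe injury).
#' @param seed integer seed.
#' @return a `lesion_overlap` with a `foci` attribute recording centres and
#'   radii.
#' @export
make_lesion_cohort <- function(geometry, n_patients, foci = 3L, radius_mm = 15, seed = 1L) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop_invalid("radius_mm must be > 0")
  if (n_patients < 1) stop_invalid("need at least one patient")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- geometry$n_nodes
  # equivalent-sphere radius of each parcel from its voxel volume (2 mm voxels)
  node_r <- (3 * (8 * geometry$node_volumes) / (4 * pi))^(1 / 3)
  overlap <- matrix(0, n_patients, n)
  centres <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    ctr_idx <- sample.int(n, foci, replace = foci > n)
    centres[[p]] <- geometry$centroids[ctr_idx, , drop = FALSE]
    for (f in seq_len(foci)) {
      d <- sqrt(colSums((t(geometry$centroids) - centres[[p]][f, ])^2))
      frac <- sphere_overlap_fraction(d, radius_mm, node_r)
      overlap[p, ] <- overlap[p, ] + frac
    }
  }
  overlap <- pmin(overlap, 1)
  out <- lesion_overlap(overlap, node_volumes = geometry$node_volumes)
  attr(out, "foci") <- list(centres = centres, radius_mm = radius_mm)
  out
}

# fraction of a node sphere (radius rn, centre distance d from the lesion
# centre) covered by a lesion sphere of radius rl: closed-form sphere-sphere
# intersection volume divided by the node sphere volume
sphere_overlap_fraction <- function(d, rl, rn) {
  vol_n <- (4 / 3) * pi * rn^3
  out <- numeric(length(d))
  full <- d <= abs(rl - rn) & rl >= rn          # node inside lesion
  sub <- d <= abs(rl - rn) & rl < rn            # lesion inside node
  lens <- d > abs(rl - rn) & d < rl + rn
  out[full] <- 1
  out[sub] <- ((4 / 3) * pi * rl^3) / vol_n[sub]
  if (any(lens)) {
    dd <- d[lens]; rnn <- rn[lens]
    v <- pi * (rl + rnn - dd)^2 *
      (dd^2 + 2 * dd * (rl + rnn) - 3 * (rl - rnn)^2) / (12 * dd)
    out[lens] <- v / vol_n[lens]
  }
  pmin(pmax(out, 0), 1)
}

#' Lesion-parcel overlap from labelled voxel grids
#'
#' For each patient, the fraction of every parcel covered by the lesion:
#' lesioned voxels inside parcel n divided by the parcel's voxel count.
#' Grids must share shape and alignment. Inputs may be arrays or NIfTI file
#' paths (read via the RNifti package when installed).
#'
#' @param lesions one 3D logical/0-1 array, a list of them (one per
#'   patient), or NIfTI file paths.
#' @param parcellation 3D integer array of parcel labels (0 = background),
#'   or a NIfTI file path.
#' @param patient_ids optional patient identifiers.
#' @return a `lesion_overlap`.
#' @export
compute_overlap <- function(lesions, parcellation, patient_ids = NULL) {
  parcellation <- as_voxel_grid(parcellation)
  if (is.character(lesions)) lesions <- as.list(lesions)
  if (!is.list(lesions)) lesions <- list(lesions)
  lesions <- lapply(lesions, as_voxel_grid)
  for (l in lesions) {
    if (!all(dim(l) == dim(parcellation))) {
      stop_invalid("lesion and parcellation grids are misaligned (different shapes)")
    }
  }
  labels <- sort(unique(as.integer(parcellation[parcellation > 0])))
  n <- max(labels)
  pvec <- as.integer(parcellation)
  vol <- tabulate(pvec, nbins = n)
  overlap <- t(vapply(lesions, function(l) {
    hit <- tabulate(pvec[as.logical(l)], nbins = n)
    ifelse(vol > 0, hit / vol, 0)
  }, numeric(n)))
  lesion_overlap(overlap, node_volumes = vol, patient_ids = patient_ids)
}

as_voxel_grid <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop_invalid("reading NIfTI files requires the RNifti package")
    }
    x <- RNifti::asNifti(RNifti::readNifti(x))
  }
  x <- unclass(x)
  if (!is.array(x) || length(dim(x)) != 3L) stop_invalid("voxel grids must be 3D arrays")
  x
}

#' Nodes to attack at an SD threshold of lesion overlap
#'
#' The attack threshold is tau = mean + k_sd * SD of all positive overlap
#' fractions pooled across patients and nodes (population SD); a node is
#' attacked for a patient when its overlap reaches tau (inclusive). Raising
#' k_sd can only shrink the attack sets.
#'
#' @param table a `lesion_overlap` (or patients x nodes matrix).
#' @param k_sd threshold in SD units (> 0); the study grid is 1.5, 2, 3, 4.
#' @return object of class `attack_set`: list with `per_patient` (list of
#'   node index vectors), `union` (unique attacked nodes), `freq` (per-node
#'   number of patients attacked), `threshold`, `k_sd`, `n_patients`.
#' @export
nodes_to_attack <- function(table, k_sd) {
  if (inherits(table, "lesion_overlap")) table <- table$overlap
  table <- as.matrix(table)
  if (!is.numeric(k_sd) || length(k_sd) != 1L || k_sd <= 0) stop_invalid("k_sd must be > 0")
  pos <- table[table > 0]
  if (length(pos) == 0) {
    warning("all overlaps are zero: empty attack sets", call. = FALSE)
    tau <- Inf
  } else {
    m <- mean(pos)
    tau <- m + k_sd * sqrt(mean((pos - m)^2))
  }
  per_patient <- lapply(seq_len(nrow(table)), function(p) which(table[p, ] >= tau))
  freq <- tabulate(unlist(per_patient), nbins = ncol(table))
  structure(
    list(per_patient = per_patient, union = which(freq > 0), freq = freq,
         threshold = tau, k_sd = k_sd, n_patients = nrow(table)),
    class = "attack_set"
  )
}

#' @export
print.attack_set <- function(x, ...) {
  cat("<attack_set> k_sd = ", x$k_sd, ", threshold = ", signif(x$threshold, 4),
      ", ", length(x$union), " unique node(s) across ", x$n_patients,
      " patient(s)\n", sep = "")
  invisible(x)
}

#' Lesion mask matrix from an attack set
#'
#' Converts attacked nodes into a multiplicative N x N disconnection mask.
#' Binary mode deletes every connection of an attacked node (factor 0);
#' weighted mode downregulates it by the lesion frequency, factor
#' 1 - freq_n / n_patients. Unattacked nodes have factor 1. A pair's mask
#' entry combines its endpoint factors with `pair_combine` ("min" avoids
#' double-penalising pairs whose both endpoints are attacked; "product" is
#' the alternative).
#'
#' @param attack an `attack_set`, or a list of per-patient node index
#'   vectors.
#' @param n_nodes number of nodes.
#' @param n_patients total number of patients (taken from `attack` when it
#'   is an `attack_set`).
#' @param mode "binary" or "weighted".
#' @param pair_combine "min" (default) or "product".
#' @return object of class `lesion_mask`: list with `M` (N x N factors in
#'   \[0, 1\]), `mode`, `node_factors`, `attacked` (node indices).
#' @export
lesion_mask_matrix <- function(attack, n_nodes, n_patients = NULL,
                               mode = c("binary", "weighted"),
                               pair_combine = c("min", "product")) {
  mode <- match.arg(mode)
  pair_combine <- match.arg(pair_combine)
  if (inherits(attack, "attack_set")) {
    freq <- attack$freq
    if (length(freq) < n_nodes) freq <- c(freq, rep(0L, n_nodes - length(freq)))
    n_patients <- attack$n_patients
  } else {
    if (is.null(n_patients)) stop_invalid("n_patients required for a plain attack list")
    freq <- tabulate(unlist(attack), nbins = n_nodes)
  }
  attacked <- which(freq > 0)
  f <- rep(1, n_nodes)
  f[attacked] <- if (mode == "binary") 0 else 1 - freq[attacked] / n_patients
  M <- if (pair_combine == "min") outer(f, f, pmin) else outer(f, f)
  structure(
    list(M = M, mode = mode, node_factors = f, attacked = attacked,
         pair_combine = pair_combine),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", x$mode, " mode, ", length(x$attacked), " attacked node(s)\n", sep = "")
  invisible(x)
}

#' Apply a simulated attack to a structural connectome
#'
#' Multiplies the connectome elementwise by the lesion mask matrix; the
#' result is flagged with provenance "attacked". Weights can only decrease.
#'
#' @param connectome a `structural_connectome`.
#' @param mask a `lesion_mask` of matching size.
#' @return a `structural_connectome` with the attacked weights.
#' @export
apply_attack <- function(connectome, mask) {
  stopifnot(inherits(connectome, "structural_connectome"), inherits(mask, "lesion_mask"))
  if (!all(dim(mask$M) == dim(connectome$C))) stop_invalid("mask and connectome shapes differ")
  out <- connectome
  out$C <- connectome$C * mask$M
  out$provenance <- "attacked"
  out
}
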