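#' Synthetic two-group BOLD cohort
#'
#' Generates a control-like and an injury-like group of subjects with the
#' Hopf simulator on an exponential-distance-rule connectome, emulating the
#' shape of the study data (145 volumes at TR = 2 s). Both groups share the
#' geometry and per-node intrinsic frequencies; the injury-like group is
#' simulated at a strictly lower global coupling and on a connectome
#' weakened by a weighted 1.5-SD simulated lesion attack built from a
#' synthetic focal-lesion cohort. Subjects at the same index in the two
#' groups share their noise seed, so group contrasts are paired at the
#' seed level.
#'
#' @param geometry a `parcel_geometry`.
#' @param n_per_group subjects per group.
#' @param G_control,G_injury global coupling per group, both in \[0, 3\] with
#'   `G_injury < G_control` (defaults 1.4 and 0.8).
#' @param n_volumes volumes per subject (>= 50; default 145).
#' @param TR repetition time in s (default 2).
#' @param seed integer seed; cohorts are bit-reproducible given the seed.
#' @param foci,radius_mm lesion geometry for the injury-like group (see
#'   [make_lesion_cohort()]).
#' @param freq_range_hz range of per-node intrinsic frequencies in Hz
#'   (default 0.03-0.07, inside the analysis band).
#' @return object of class `synthetic_cohort`: list with `bold` (named list
#'   of N x T matrices), `manifest` (tibble: subject, group, G_true, seed,
#'   TR, n_volumes), `geometry`, `connectomes` (list control / injury),
#'   `lesions` (a `lesion_overlap`), `omega`, `TR`.
#' @export
make_cohort <- function(geometry, n_per_group, G_control = 1.4, G_injury = 0.8,
                        n_volumes = 145L, TR = 2, seed = 1L,
                        foci = 3L, radius_mm = 15, freq_range_hz = c(0.03, 0.07)) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (!(G_injury < G_control)) stop_invalid("G_injury must be strictly below G_control")
  if (G_control < 0 || G_control > 3 || G_injury < 0 || G_injury > 3) {
    stop_invalid("G values must lie in the sweep range [0, 3]")
  }
  if (n_volumes < 50) stop_invalid("need at least 50 volumes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  omega <- 2 * pi * runif(geometry$n_nodes, freq_range_hz[1], freq_range_hz[2])
  lesion_seed <- draw_subseeds(1L)
  subj_seeds <- draw_subseeds(n_per_group)

  conn_control <- build_edr_connectome(geometry)
  lesions <- make_lesion_cohort(geometry, n_patients = n_per_group,
                                foci = foci, radius_mm = radius_mm, seed = lesion_seed)
  attack <- nodes_to_attack(lesions, k_sd = 1.5)
  mask <- lesion_mask_matrix(attack, n_nodes = geometry$n_nodes, mode = "weighted")
  conn_injury <- apply_attack(conn_control, mask)

  simulate_group <- function(conn, G, tag) {
    lapply(seq_len(n_per_group), function(i) {
      cfg <- hopf_config(omega = omega, G = G, n_volumes = n_volumes, TR = TR,
                         seed = subj_seeds[i])
      simulate_hopf(conn, cfg)$values
    })
  }
  bold <- c(simulate_group(conn_control, G_control, "control"),
            simulate_group(conn_injury, G_injury, "injury"))
  ids <- c(sprintf("control_%02d", seq_len(n_per_group)),
           sprintf("injury_%02d", seq_len(n_per_group)))
  names(bold) <- ids
  manifest <- tibble::tibble(
    subject = ids,
    group = rep(c("control", "injury"), each = n_per_group),
    G_true = rep(c(G_control, G_injury), each = n_per_group),
    seed = rep(subj_seeds, 2L),
    TR = TR,
    n_volumes = as.integer(n_volumes)
  )
  structure(
    list(bold = bold, manifest = manifest, geometry = geometry,
         connectomes = list(control = conn_control, injury = conn_injury),
         lesions = lesions, attack = attack, omega = omega, TR = TR),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$bold), " subjects (",
      sum(x$manifest$group == "control"), " control-like, ",
      sum(x$manifest$group == "injury"), " injury-like), ",
      x$geometry$n_nodes, " nodes x ", x$manifest$n_volumes[1],
      " volumes, TR = ", x$TR, " s\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic cohort as delimited text
#'
#' One tab-separated BOLD matrix per subject plus a `manifest.tsv` (subject,
#' group, ground-truth G, seed, TR, volumes) and the geometry table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `read_cohort` returns a list with `bold`, `manifest`, `geometry`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$bold)) {
    utils::write.table(cohort$bold[[id]], file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(as.data.frame(cohort$manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_geometry(cohort$geometry, file.path(dir, "geometry.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- tibble::as_tibble(utils::read.table(file.path(dir, "manifest.tsv"),
                                                  header = TRUE, sep = "\t",
                                                  stringsAsFactors = FALSE))
  bold <- lapply(manifest$subject, function(id) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(id, ".tsv")), sep = "\t"))
    dimnames(m) <- NULL
    m
  })
  names(bold) <- manifest$subject
  list(bold = bold, manifest = manifest,
       geometry = read_geometry(file.path(dir, "geometry.tsv")))
}

#' Per-subject turbulence for a cohort
#'
#' Convenience wrapper running band-pass, phase extraction and amplitude
#' turbulence at one spatial scale for every subject of a cohort.
#'
#' @param cohort a `synthetic_cohort` (or the list returned by
#'   [read_cohort()]).
#' @param lambda spatial scale in mm^-1.
#' @return tibble with columns subject, group, turbulence.
#' @export
cohort_turbulence <- function(cohort, lambda = 0.03) {
  distances <- cohort$geometry$distances
  TR <- cohort$manifest$TR[1]
  vals <- purrr::map_dbl(cohort$bold, function(b) {
    ph <- extract_phases(bandpass(bold_ts(b, TR)))
    amplitude_turbulence(local_order(ph, distances, lambda))
  })
  tibble::tibble(subject = cohort$manifest$subject,
                 group = cohort$manifest$group,
                 turbulence = unname(vals))
}
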