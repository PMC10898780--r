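#' Structural connectome from the exponential distance rule
#'
#' Builds the coupling matrix C_np = exp(-lambda_c r_np) from the pairwise
#' Euclidean distances of a parcel geometry. lambda_c = 0.18 mm^-1 is the
#' decay that best reproduces empirical whole-brain fits in this framework
#' (distinct from the turbulence scale lambda). When an empirical
#' structural-connectivity matrix is supplied it is max-normalised and used
#' as long-range exceptions: each weight becomes
#' max(exp(-lambda_c r), SC_np), restoring strong empirical connections the
#' distance rule under-predicts. The diagonal is set to zero.
#'
#' @param geometry a `parcel_geometry`, or an N x N distance matrix in mm.
#' @param lambda_c exponential decay in mm^-1 (> 0), default 0.18.
#' @param empirical_sc optional nonnegative N x N matrix of empirical
#'   structural connectivity.
#' @return object of class `structural_connectome`: list with `C` (N x N
#'   weights), `distances`, `lambda_c`, `provenance` (one of "edr",
#'   "edr+lr", "attacked", "external"), and `geometry` (possibly NULL).
#' @export
build_edr_connectome <- function(geometry, lambda_c = 0.18, empirical_sc = NULL) {
  if (inherits(geometry, "parcel_geometry")) {
    distances <- geometry$distances
    geom <- geometry
  } else {
    distances <- as.matrix(geometry)
    geom <- NULL
  }
  if (!is.numeric(lambda_c) || length(lambda_c) != 1L || lambda_c <= 0) {
    stop_invalid("lambda_c must be a positive scalar (mm^-1)")
  }
  n <- nrow(distances)
  off <- distances[upper.tri(distances)]
  if (any(off == 0)) {
    warning("degenerate geometry: coincident centroids (zero off-diagonal distance)", call. = FALSE)
  }
  C <- exp(-lambda_c * distances)
  provenance <- "edr"
  if (!is.null(empirical_sc)) {
    empirical_sc <- as.matrix(empirical_sc)
    if (!all(dim(empirical_sc) == c(n, n))) stop_invalid("empirical_sc shape mismatch")
    if (any(empirical_sc < 0)) stop_invalid("empirical_sc must be nonnegative")
    # bring weights onto the [0, 1] scale of the EDR; matrices already on
    # that scale are left untouched
    if (max(empirical_sc) > 1) empirical_sc <- empirical_sc / max(empirical_sc)
    sc <- (empirical_sc + t(empirical_sc)) / 2
    C <- pmax(C, sc)
    provenance <- "edr+lr"
  }
  diag(C) <- 0
  structure(
    list(C = C, distances = distances, lambda_c = lambda_c,
         provenance = provenance, geometry = geom),
    class = "structural_connectome"
  )
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat("<structural_connectome> ", nrow(x$C), " nodes, provenance = ",
      x$provenance, ", lambda_c = ", x$lambda_c, "\n", sep = "")
  invisible(x)
}

#' Write / read a structural connectome as a delimited matrix
#'
#' The square weight matrix is stored as tab-separated text; `lambda_c` and
#' provenance travel in a `<path>.meta` sidecar.
#'
#' @param connectome a `structural_connectome`.
#' @param path file path.
#' @param distances optional distance matrix to re-attach on read.
#' @export
write_connectome <- function(connectome, path) {
  stopifnot(inherits(connectome, "structural_connectome"))
  utils::write.table(connectome$C, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  writeLines(c(paste0("lambda_c\t", connectome$lambda_c),
               paste0("provenance\t", connectome$provenance)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, distances = NULL) {
  C <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(C) <- NULL
  meta <- utils::read.table(paste0(path, ".meta"), sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  structure(
    list(C = C, distances = distances,
         lambda_c = as.numeric(meta$V2[meta$V1 == "lambda_c"]),
         provenance = meta$V2[meta$V1 == "provenance"], geometry = NULL),
    class = "structural_connectome"
  )
}

#' Intrinsic node frequencies from band-passed BOLD
#'
#' Each node's angular frequency omega_n for the Hopf model is taken as
#' 2 pi times the peak of its periodogram inside the analysis band
#' 0.008-0.08 Hz. Flat spectra (no variance in band) fall back to the band
#' midpoint with a warning.
#'
#' @param ts a band-passed `bold_ts` with at least 32 volumes.
#' @param band frequency band searched for the spectral peak, Hz.
#' @return numeric vector of omega_n in rad/s, with the peak frequencies in
#'   Hz attached as attribute `f_hz`.
#' @export
estimate_frequencies <- function(ts, band = c(0.008, 0.08)) {
  stopifnot(inherits(ts, "bold_ts"))
  x <- ts$values
  if (ncol(x) < 32) stop_invalid("need at least 32 volumes to estimate spectra")
  fs <- 1 / ts$TR
  n <- ncol(x)
  freqs <- (seq_len(floor(n / 2))) * fs / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop_invalid("no frequency bins inside the band")
  f_hz <- apply(x, 1L, function(row) {
    row <- row - mean(row)
    pw <- Mod(fft(row))[2:(floor(n / 2) + 1)]^2
    pb <- pw[in_band]
    if (max(pb) <= 0 || !any(is.finite(pb))) return(NA_real_)
    freqs[in_band][which.max(pb)]
  })
  flat <- is.na(f_hz)
  if (any(flat)) {
    warning(sum(flat), " node(s) had a flat spectrum; using the band midpoint", call. = FALSE)
    f_hz[flat] <- mean(band)
  }
  omega <- 2 * pi * f_hz
  attr(omega, "f_hz") <- f_hz
  omega
}

#' Hopf model configuration
#'
#' Parameters of the coupled Stuart-Landau system. The bifurcation
#' parameter a_n switches each node between a noisy fixed point (a < 0) and
#' a self-sustained limit cycle (a > 0); the resting baseline is a_n = -0.02
#' for all nodes. G scales all structural couplings; nu is the additive
#' Gaussian noise standard deviation (0.01). Integration uses
#' Euler-Maruyama at step `dt` seconds, discards `burn_in` seconds, and
#' decimates the x component to the scanner TR by stride.
#'
#' @param omega per-node angular frequencies, rad/s.
#' @param a bifurcation parameter, scalar or per-node (default -0.02).
#' @param G global coupling (dimensionless, >= 0).
#' @param nu noise standard deviation (default 0.01).
#' @param dt integrator step in s (default 0.1).
#' @param n_volumes number of output volumes (default 145).
#' @param TR output sampling interval in s (default 2).
#' @param burn_in discarded transient in s (default 20).
#' @param seed optional integer seed for the noise realisation.
#' @param init optional list(x, y) of initial conditions; by default small
#'   Gaussian perturbations around the origin.
#' @return object of class `hopf_config`.
#' @export
hopf_config <- function(omega, a = -0.02, G = 1, nu = 0.01, dt = 0.1,
                        n_volumes = 145L, TR = 2, burn_in = 20, seed = NULL,
                        init = NULL) {
  if (any(nu < 0)) stop_invalid("nu must be >= 0")
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (burn_in < 0) stop_invalid("burn_in must be >= 0")
  if (G < 0) stop_invalid("G must be >= 0")
  structure(
    list(omega = as.numeric(omega), a = as.numeric(a), G = G, nu = nu, dt = dt,
         n_volumes = as.integer(n_volumes), TR = TR, burn_in = burn_in,
         seed = seed, init = init),
    class = "hopf_config"
  )
}

#' Simulate whole-brain Hopf dynamics
#'
#' Integrates the coupled Stuart-Landau system on a structural connectome
#' with Euler-Maruyama, discards the burn-in, and returns the real part x_n
#' decimated to the TR as BOLD-like signal (the imaginary component, the
#' oscillator state hidden from the scanner, is attached as attribute
#' `hidden`). Runs are bit-reproducible for a fixed `seed` in the config.
#'
#' @param connectome a `structural_connectome` (or plain N x N matrix).
#' @param config a `hopf_config`; `omega` and `a` must match the connectome
#'   size (scalars are recycled).
#' @return a `bold_ts` of dimension N x n_volumes.
#' @export
simulate_hopf <- function(connectome, config) {
  stopifnot(inherits(config, "hopf_config"))
  C <- if (inherits(connectome, "structural_connectome")) connectome$C else as.matrix(connectome)
  n <- nrow(C)
  omega <- rep_len(config$omega, n)
  a <- rep_len(config$a, n)
  if (!(length(config$omega) %in% c(1L, n))) stop_invalid("omega length must be 1 or N")
  if (!(length(config$a) %in% c(1L, n))) stop_invalid("a length must be 1 or N")
  stride <- max(1L, as.integer(round(config$TR / config$dt)))
  burn_steps <- as.integer(round(config$burn_in / config$dt))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  if (is.null(config$init)) {
    x0 <- rnorm(n, 0, 0.1)
    y0 <- rnorm(n, 0, 0.1)
  } else {
    x0 <- rep_len(config$init$x, n)
    y0 <- rep_len(config$init$y, n)
  }
  sim <- hopf_integrate_cpp(C, a, omega, config$G, config$nu, config$dt,
                            burn_steps, config$n_volumes, stride, x0, y0)
  out <- bold_ts(sim$x, config$TR)
  attr(out, "hidden") <- sim$y
  out
}
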