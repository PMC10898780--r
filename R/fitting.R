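#' Distance-resolved functional connectivity profile
#'
#' Node signals are z-scored, the Pearson correlation is computed for every
#' node pair, and the pair correlations are averaged inside equal-width
#' distance bins within `range_mm`: FC(r). Kolmogorov's structure function
#' follows as S(r) = 2 (FC(0) - FC(r)) = 2 (1 - FC(r)), since z-scored
#' signals have FC(0) = 1. Zero-variance nodes are excluded and counted.
#'
#' @param ts a `bold_ts` (or N x T matrix).
#' @param distances N x N Euclidean distance matrix in mm.
#' @param bins number of equal-width distance bins (default 50).
#' @param range_mm distance range of the profile, c(lo, hi) in mm; this is
#'   also the inertial subrange used by [fitting_error()].
#' @return object of class `fc_profile`: a tibble with columns bin, r_mid,
#'   fc, s, n_pairs, plus attributes `range_mm`, `bins`, `n_excluded`.
#' @export
fc_profile <- function(ts, distances, bins = 50L, range_mm = c(10, 100)) {
  x <- if (inherits(ts, "bold_ts")) ts$values else as.matrix(ts)
  if (ncol(x) < 3) stop_invalid("need at least 3 volumes")
  distances <- as.matrix(distances)
  if (nrow(x) != nrow(distances)) stop_invalid("ts and distances have different node counts")
  v <- apply(x, 1L, stats::var)
  ok <- v > 0
  n_excluded <- sum(!ok)
  if (sum(ok) < 2) stop_invalid("fewer than 2 nodes with nonzero variance")
  z <- t(scale(t(x[ok, , drop = FALSE])))
  cormat <- stats::cor(t(z))
  dd <- distances[ok, ok, drop = FALSE]
  iu <- upper.tri(dd)
  d <- dd[iu]
  cc <- cormat[iu]
  keep <- d >= range_mm[1] & d <= range_mm[2]
  prof <- bin_mean(d[keep], cc[keep], bins, range_mm)
  prof <- dplyr::transmute(prof, bin = .data$bin, r_mid = .data$r_mid,
                           fc = .data$value, s = 2 * (1 - .data$value),
                           n_pairs = .data$n_pairs)
  structure(prof, class = c("fc_profile", class(prof)),
            range_mm = range_mm, bins = as.integer(bins), n_excluded = n_excluded)
}

#' Group-averaged FC profile
#'
#' Computes one distance-resolved FC profile per subject and averages FC(r)
#' bin-wise across subjects — the condition-level empirical target used
#' when fitting the global coupling.
#'
#' @param bold list of N x T BOLD matrices (or `bold_ts` objects).
#' @param distances shared N x N distance matrix in mm.
#' @param bins,range_mm as in [fc_profile()].
#' @return an `fc_profile` (bins present in every subject are kept).
#' @export
group_fc_profile <- function(bold, distances, bins = 50L, range_mm = c(10, 100)) {
  stopifnot(is.list(bold), length(bold) >= 1L)
  profs <- lapply(bold, function(b) {
    x <- if (inherits(b, "bold_ts")) b else bold_ts(b, TR = 1)
    fc_profile(x, distances, bins, range_mm)
  })
  shared <- Reduce(intersect, lapply(profs, function(p) p$bin))
  fcm <- rowMeans(sapply(profs, function(p) p$fc[match(shared, p$bin)]))
  base <- profs[[1]][match(shared, profs[[1]]$bin), ]
  base$fc <- fcm
  base$s <- 2 * (1 - fcm)
  base$n_pairs <- as.integer(round(rowMeans(
    sapply(profs, function(p) p$n_pairs[match(shared, p$bin)])
  )))
  base
}

#' Fitting error between two FC profiles
#'
#' The Euclidean distance between simulated and empirical FC(r) over the
#' bins of the shared inertial subrange: sqrt(sum over bins of squared
#' differences). Profiles must be built on the same bin grid; bins empty in
#' either profile are dropped from the sum.
#'
#' @param sim,emp `fc_profile` objects on identical bin grids.
#' @return nonnegative scalar.
#' @export
fitting_error <- function(sim, emp) {
  stopifnot(inherits(sim, "fc_profile"), inherits(emp, "fc_profile"))
  if (!isTRUE(all.equal(attr(sim, "range_mm"), attr(emp, "range_mm"))) ||
      attr(sim, "bins") != attr(emp, "bins")) {
    stop_invalid("profiles were built on different bin grids")
  }
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(sim), "bin", fc_sim = "fc"),
    dplyr::select(tibble::as_tibble(emp), "bin", fc_emp = "fc"),
    by = "bin"
  )
  if (nrow(m) == 0) stop_invalid("no shared non-empty bins")
  sqrt(sum((m$fc_sim - m$fc_emp)^2))
}

#' Grid sweep of the global coupling G
#'
#' For every G on the grid, the Hopf model is simulated `reps` times with
#' distinct sub-seeds, each run's distance-resolved FC profile is compared
#' with the empirical profile via [fitting_error()], and the errors are
#' averaged. The working point G* is the grid value minimising the mean
#' error (ties broken toward smaller G). Diverged simulations are dropped
#' and counted; a G where every repetition diverges is an error.
#'
#' @param connectome a `structural_connectome`.
#' @param config a `hopf_config` template; its `G` and `seed` are overridden
#'   per run.
#' @param empirical an `fc_profile` of the data being fitted.
#' @param G_grid coupling grid (default 0 to 3 by 0.01, the full sweep).
#' @param reps simulations per grid value (default 100).
#' @param seed integer seed controlling all sub-seeds.
#' @return object of class `g_sweep`: list with `curve` (tibble G,
#'   mean_error, n_ok), `per_rep` (tibble G, rep, error), `G_star`,
#'   `min_error`, `reps`, `seed`, `n_diverged`.
#' @export
sweep_G <- function(connectome, config, empirical, G_grid = seq(0, 3, by = 0.01),
                    reps = 100L, seed = 1L) {
  stopifnot(inherits(config, "hopf_config"), inherits(empirical, "fc_profile"))
  if (length(G_grid) < 1L) stop_invalid("G grid must be nonempty")
  if (reps < 1L) stop_invalid("reps must be >= 1")
  G_grid <- sort(as.numeric(G_grid))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # one sub-seed per repetition, shared across the grid: common random
  # numbers make the error curve smooth in G, stabilising the argmin
  subseeds <- matrix(draw_subseeds(reps), nrow = reps, ncol = length(G_grid))
  range_mm <- attr(empirical, "range_mm")
  bins <- attr(empirical, "bins")
  n_diverged <- 0L
  per_rep <- purrr::map_dfr(seq_along(G_grid), function(gi) {
    errs <- vapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$G <- G_grid[gi]
      cfg$seed <- subseeds[r, gi]
      sim <- tryCatch(simulate_hopf(connectome, cfg), error = function(e) {
        if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
      })
      if (is.null(sim)) return(NA_real_)
      fitting_error(fc_profile(sim, connectome$distances, bins, range_mm), empirical)
    }, numeric(1))
    tibble::tibble(G = G_grid[gi], rep = seq_len(reps), error = errs)
  })
  n_diverged <- sum(is.na(per_rep$error))
  if (n_diverged > 0) {
    warning(n_diverged, " diverged simulation(s) excluded from the sweep", call. = FALSE)
  }
  curve <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$G),
    mean_error = mean(.data$error, na.rm = TRUE),
    n_ok = sum(!is.na(.data$error)), .groups = "drop"
  )
  if (any(curve$n_ok == 0)) {
    stop_invalid("all repetitions diverged at G = ",
                 paste(curve$G[curve$n_ok == 0], collapse = ", "))
  }
  best <- which.min(curve$mean_error)
  structure(
    list(curve = curve, per_rep = per_rep, G_star = curve$G[best],
         min_error = curve$mean_error[best], reps = as.integer(reps),
         seed = as.integer(seed), n_diverged = n_diverged),
    class = "g_sweep"
  )
}

#' @export
print.g_sweep <- function(x, ...) {
  cat("<g_sweep> ", nrow(x$curve), " grid values x ", x$reps,
      " reps; G* = ", x$G_star, " (error ", signif(x$min_error, 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname sweep_G
#' @param x a `g_sweep`.
#' @param ... unused.
#' @export
tidy.g_sweep <- function(x, ...) x$curve

#' @rdname sweep_G
#' @export
glance.g_sweep <- function(x, ...) {
  tibble::tibble(G_star = x$G_star, min_error = x$min_error,
                 reps = x$reps, n_grid = nrow(x$curve), n_diverged = x$n_diverged)
}

#' Plot the fitting-error curve of a coupling sweep
#'
#' @param object a `g_sweep`.
#' @param ... unused.
#' @return ggplot of mean fitting error versus G with the working point marked.
#' @export
autoplot.g_sweep <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$G, y = .data$mean_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$G_star, linetype = 2) +
    ggplot2::labs(x = "Global coupling G", y = "FC(r) fitting error",
                  subtitle = paste0("G* = ", object$G_star)) +
    ggplot2::theme_minimal()
}

#' Compare fitted working points across conditions
#'
#' Pure reporting (no inference): one row per condition with its fitted
#' working point and minimum error, ordered as given.
#'
#' @param ... named `g_sweep` objects, or a single named list of them.
#' @return tibble with columns condition, G_star, min_error.
#' @export
compare_working_points <- function(...) {
  sweeps <- list(...)
  if (length(sweeps) == 1L && !inherits(sweeps[[1]], "g_sweep")) sweeps <- sweeps[[1]]
  if (length(sweeps) < 2L) stop_invalid("need at least two sweeps to compare")
  stopifnot(all(vapply(sweeps, inherits, logical(1), "g_sweep")))
  nm <- names(sweeps)
  if (is.null(nm) || any(nm == "")) nm <- paste0("condition_", seq_along(sweeps))
  purrr::map2_dfr(sweeps, nm, function(s, n) {
    tibble::tibble(condition = n, G_star = s$G_star, min_error = s$min_error)
  })
}
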