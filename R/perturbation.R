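#' In silico perturbation protocol
#'
#' Settings of the random bifurcation-parameter perturbation applied to a
#' fitted Hopf model. Each trial redraws every node's bifurcation parameter
#' uniformly inside `a_range` (default \[-0.02, 0\], i.e. from the resting
#' baseline up to criticality) and compares the perturbed run against an
#' unperturbed one. With `paired_seeds` the two runs of a trial share their
#' noise realisation, which makes the null (zero-width range) difference
#' exactly zero and greatly reduces Monte-Carlo variance.
#'
#' @param a_range perturbation interval for a_n, lower <= upper <= 0.
#' @param trials number of perturbation trials (default 100).
#' @param lambda_s spatial scale of the local order parameter used by the
#'   perturbational measures (default 0.01, the long-distance scale).
#' @param paired_seeds logical; share noise seeds between the perturbed and
#'   unperturbed run of each trial (default TRUE).
#' @param capability_moment "std" (default) or "var": the across-trial
#'   dispersion used by the information-encoding capability.
#' @return object of class `perturbation_protocol`.
#' @export
perturbation_protocol <- function(a_range = c(-0.02, 0), trials = 100L,
                                  lambda_s = 0.01, paired_seeds = TRUE,
                                  capability_moment = c("std", "var")) {
  capability_moment <- match.arg(capability_moment)
  if (length(a_range) != 2L || a_range[1] > a_range[2] || a_range[2] > 0) {
    stop_invalid("a_range must satisfy lower <= upper <= 0")
  }
  if (trials < 1L) stop_invalid("trials must be >= 1")
  if (lambda_s <= 0) stop_invalid("lambda_s must be > 0")
  structure(
    list(a_range = as.numeric(a_range), trials = as.integer(trials),
         lambda_s = lambda_s, paired_seeds = isTRUE(paired_seeds),
         capability_moment = capability_moment),
    class = "perturbation_protocol"
  )
}

#' Random perturbed bifurcation parameters
#'
#' Independent uniform draw of one bifurcation parameter per node inside
#' `a_range`, consuming the current RNG stream.
#'
#' @param n_nodes number of nodes.
#' @param a_range perturbation interval (default \[-0.02, 0\]).
#' @return numeric vector of length `n_nodes`.
#' @export
draw_perturbed_bifurcation <- function(n_nodes, a_range = c(-0.02, 0)) {
  if (length(a_range) != 2L || a_range[1] > a_range[2]) {
    stop_invalid("a_range must be an interval c(lower, upper)")
  }
  runif(n_nodes, a_range[1], a_range[2])
}

#' Run the in silico perturbation experiment
#'
#' For every trial, the model at the fitted working point is simulated
#' twice: once at the baseline bifurcation parameters and once with
#' per-node parameters redrawn inside the protocol's range. Both runs go
#' through the empirical pipeline (band-pass, analytic-signal phases,
#' local order parameter at `lambda_s`), and the trial yields each node's
#' difference in time-averaged R. Susceptibility chi is the node average of
#' the trial-mean difference (how strongly the brain model reacts to the
#' stimulation); the information-encoding capability I is the node average
#' of the across-trial dispersion of that difference (how distinguishably
#' stimuli are encoded). Diverged trials are dropped and counted; more
#' than 20% dropped is an error.
#'
#' @param connectome a `structural_connectome` (with distances).
#' @param config a `hopf_config` at the fitted working point G*; its `a` is
#'   the unperturbed baseline.
#' @param protocol a `perturbation_protocol`.
#' @param seed integer seed for trial sub-seeds and perturbation draws.
#' @return object of class `perturbation_result`: list with `chi`,
#'   `info_capability`, `diffs` (trials x nodes matrix of time-mean R
#'   differences), `per_trial` (tibble trial, delta: node-averaged
#'   difference), `protocol`, `n_dropped`.
#' @export
run_perturbation <- function(connectome, config, protocol = perturbation_protocol(),
                             seed = 1L) {
  stopifnot(inherits(config, "hopf_config"), inherits(protocol, "perturbation_protocol"))
  distances <- if (inherits(connectome, "structural_connectome")) {
    connectome$distances
  } else {
    stop_invalid("connectome must be a structural_connectome carrying distances")
  }
  n <- nrow(connectome$C)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  trial_seeds <- matrix(draw_subseeds(2L * protocol$trials), ncol = 2L)
  if (protocol$paired_seeds) trial_seeds[, 2] <- trial_seeds[, 1]
  a_draws <- t(vapply(seq_len(protocol$trials), function(i) {
    draw_perturbed_bifurcation(n, protocol$a_range)
  }, numeric(n)))

  mean_R <- function(cfg) {
    sim <- simulate_hopf(connectome, cfg)
    ph <- extract_phases(bandpass(sim))
    rowMeans(local_order(ph, distances, protocol$lambda_s)$R)
  }
  diffs <- matrix(NA_real_, protocol$trials, n)
  for (i in seq_len(protocol$trials)) {
    cfg_un <- config
    cfg_un$seed <- trial_seeds[i, 2]
    cfg_pe <- config
    cfg_pe$seed <- trial_seeds[i, 1]
    cfg_pe$a <- a_draws[i, ]
    res <- tryCatch(mean_R(cfg_pe) - mean_R(cfg_un), error = function(e) {
      if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
    })
    if (!is.null(res)) diffs[i, ] <- res
  }
  dropped <- which(apply(diffs, 1L, anyNA))
  n_dropped <- length(dropped)
  if (n_dropped > 0.2 * protocol$trials) {
    stop_invalid(n_dropped, " of ", protocol$trials, " trials diverged (> 20%)")
  }
  if (n_dropped > 0) diffs <- diffs[-dropped, , drop = FALSE]
  structure(
    list(chi = susceptibility_stat(diffs),
         info_capability = capability_stat(diffs, protocol$capability_moment),
         diffs = diffs,
         per_trial = tibble::tibble(trial = seq_len(nrow(diffs)),
                                    delta = rowMeans(diffs)),
         protocol = protocol, n_dropped = n_dropped, seed = as.integer(seed)),
    class = "perturbation_result"
  )
}

#' Susceptibility and capability statistics from cached trials
#'
#' The aggregation step of the perturbational measures, separated out so it
#' can be applied to any trials x nodes matrix of perturbed-minus-
#' unperturbed time-mean local order parameters: `susceptibility_stat` is
#' the average over nodes of the average over trials; `capability_stat` is
#' the average over nodes of the across-trial population dispersion
#' (standard deviation by default, variance as the printed alternative).
#'
#' @param diffs trials x nodes matrix of differences.
#' @param moment "std" or "var".
#' @return scalar.
#' @export
susceptibility_stat <- function(diffs) {
  diffs <- as.matrix(diffs)
  mean(colMeans(diffs))
}

#' @rdname susceptibility_stat
#' @export
capability_stat <- function(diffs, moment = c("std", "var")) {
  moment <- match.arg(moment)
  diffs <- as.matrix(diffs)
  if (nrow(diffs) < 2) stop_invalid("capability needs at least 2 trials")
  m <- colMeans(diffs)
  v <- colMeans(diffs^2) - m^2
  mean(if (moment == "std") sqrt(pmax(v, 0)) else pmax(v, 0))
}

#' Susceptibility of a whole-brain model
#'
#' @param x a `perturbation_result`, or a `structural_connectome` (in which
#'   case the experiment is run via [run_perturbation()] first).
#' @param ... passed on to [run_perturbation()] when `x` is a connectome.
#' @return scalar chi.
#' @export
susceptibility <- function(x, ...) {
  if (inherits(x, "perturbation_result")) return(x$chi)
  run_perturbation(x, ...)$chi
}

#' Information-encoding capability of a whole-brain model
#'
#' @inheritParams susceptibility
#' @return scalar I (>= 0).
#' @export
information_capability <- function(x, ...) {
  if (inherits(x, "perturbation_result")) return(x$info_capability)
  run_perturbation(x, ...)$info_capability
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> ", nrow(x$diffs), " trials, lambda_s = ",
      x$protocol$lambda_s, "; chi = ", signif(x$chi, 4), ", I = ",
      signif(x$info_capability, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname run_perturbation
#' @param x a `perturbation_result`.
#' @param ... unused.
#' @export
tidy.perturbation_result <- function(x, ...) x$per_trial

#' @rdname run_perturbation
#' @export
glance.perturbation_result <- function(x, ...) {
  tibble::tibble(chi = x$chi, info_capability = x$info_capability,
                 trials = nrow(x$diffs), n_dropped = x$n_dropped,
                 lambda_s = x$protocol$lambda_s)
}

#' Stack per-trial reactivity across conditions
#'
#' Combines the per-trial node-averaged differences of several perturbation
#' experiments into one long table ready for rank-sum testing (see
#' [rank_tests()]).
#'
#' @param ... named `perturbation_result` objects, or one named list.
#' @return tibble with columns condition, trial, delta.
#' @export
compare_reactivity <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "perturbation_result")) {
    results <- results[[1]]
  }
  if (length(results) < 2L) stop_invalid("need at least two conditions")
  stopifnot(all(vapply(results, inherits, logical(1), "perturbation_result")))
  nm <- names(results)
  if (is.null(nm) || any(nm == "")) nm <- paste0("condition_", seq_along(results))
  purrr::map2_dfr(results, nm, function(r, n) {
    dplyr::mutate(r$per_trial, condition = n, .before = 1)
  })
}
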