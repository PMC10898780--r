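#' Spatial-scale grid for the turbulence measures
#'
#' The exponential kernel scale lambda (mm^-1) controls the spatial reach of
#' the local order parameter: small lambda probes long distances (~100 mm at
#' 0.01), large lambda short ones (~3 mm at 0.30). The default grid runs
#' from 0.01 to 0.30 in steps of 0.03 (ten scales).
#'
#' @param from,to,by grid limits and step in mm^-1.
#' @return strictly increasing numeric vector of scales.
#' @export
scale_grid <- function(from = 0.01, to = 0.30, by = 0.03) {
  g <- seq(from, to, by = by)
  if (any(g <= 0) || any(diff(g) <= 0)) stop_invalid("scales must be positive and strictly increasing")
  g
}

#' Kuramoto local order parameter
#'
#' For every node n and volume t, the phases of all nodes are averaged as
#' unit vectors with exponential spatial weights C_np = exp(-lambda r_np)
#' (the self term C_nn = 1 included), normalised by the kernel mass:
#' R_n(t) exp(i theta_n(t)) = sum_p C_np exp(i phi_p(t)) / sum_q C_nq.
#' The modulus R in \[0, 1\] measures local synchronisation around node n at
#' spatial scale lambda.
#'
#' @param phases a `phase_field` or plain N x T matrix of phases in radians.
#' @param distances N x N Euclidean distance matrix in mm.
#' @param lambda spatial scale in mm^-1 (> 0).
#' @return object of class `local_order_field`: list with `R` (N x T moduli),
#'   `theta` (N x T phases of the local order parameter), `lambda`, `TR`.
#' @export
local_order <- function(phases, distances, lambda) {
  TR <- NA_real_
  if (inherits(phases, "phase_field")) {
    TR <- phases$TR
    phases <- phases$phases
  }
  phases <- as.matrix(phases)
  distances <- as.matrix(distances)
  if (nrow(phases) != nrow(distances) || nrow(distances) != ncol(distances)) {
    stop_invalid("phases and distances have inconsistent shapes")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop_invalid("lambda must be a positive scalar (mm^-1)")
  }
  if (!all(is.finite(phases))) {
    bad <- which(!is.finite(phases), arr.ind = TRUE)[1, ]
    stop_invalid("non-finite phase at node ", bad[1], ", time ", bad[2])
  }
  kern <- exp(-lambda * distances)
  kern <- kern / rowSums(kern)
  z <- kern %*% exp(1i * phases)
  structure(
    list(R = Mod(z), theta = Arg(z), lambda = lambda, TR = TR),
    class = "local_order_field"
  )
}

#' @export
print.local_order_field <- function(x, ...) {
  cat("<local_order_field> lambda = ", x$lambda, ", ", nrow(x$R), " nodes x ",
      ncol(x$R), " volumes\n", sep = "")
  invisible(x)
}

field_R <- function(field) {
  if (inherits(field, "local_order_field")) field$R else as.matrix(field)
}

#' Amplitude turbulence
#'
#' The standard deviation, pooled over all nodes and volumes, of the modulus
#' of the Kuramoto local order parameter: D = sqrt(<R^2> - <R>^2) with plain
#' (population) averages. D = 0 under full synchrony; larger D means more
#' spatiotemporal variability of local synchronisation.
#'
#' @param field a `local_order_field` (or an R matrix).
#' @return nonnegative scalar.
#' @export
amplitude_turbulence <- function(field) {
  R <- field_R(field)
  sqrt(max(mean(R^2) - mean(R)^2, 0))
}

#' Node-level metastability
#'
#' Per-node temporal (population) standard deviation of the local order
#' parameter modulus: the local analogue of global metastability.
#'
#' @param field a `local_order_field` (or an R matrix).
#' @return numeric vector of length N.
#' @export
node_metastability <- function(field) {
  R <- field_R(field)
  m <- rowMeans(R)
  sqrt(pmax(rowMeans(R^2) - m^2, 0))
}

#' Network-level amplitude turbulence
#'
#' Amplitude turbulence computed separately within each resting-state
#' network: the pooled node-time standard deviation of R restricted to the
#' nodes carrying each label. Networks with fewer than two nodes are
#' excluded with a warning.
#'
#' @param field a `local_order_field` (or an R matrix).
#' @param rsn_labels per-node labels (character or factor) covering all nodes.
#' @return tibble with columns network, turbulence, n_nodes.
#' @export
rsn_turbulence <- function(field, rsn_labels) {
  R <- field_R(field)
  if (length(rsn_labels) != nrow(R)) stop_invalid("labels must cover all nodes")
  labs <- as.character(rsn_labels)
  networks <- unique(labs)
  rows <- lapply(networks, function(net) {
    idx <- which(labs == net)
    if (length(idx) < 2) {
      warning("network ", net, " has < 2 nodes and is excluded", call. = FALSE)
      return(NULL)
    }
    tibble::tibble(network = net,
                   turbulence = amplitude_turbulence(R[idx, , drop = FALSE]),
                   n_nodes = length(idx))
  })
  dplyr::bind_rows(rows)
}

#' Information cascade flow between adjacent spatial scales
#'
#' The lagged temporal correlation of the local order parameter between a
#' scale lambda and the next lower scale lambda - delta-lambda: per node,
#' Pearson correlation over time of R_lambda(n, t + dt) with
#' R_(lambda-delta)(n, t), then averaged over nodes. It proxies information
#' travelling from coarser to finer scales in successive time steps.
#' Nodes with zero temporal variance in either field are excluded; their
#' count is attached as attribute `n_excluded`.
#'
#' @param field_hi `local_order_field` at the larger lambda.
#' @param field_lo `local_order_field` at the adjacent smaller lambda.
#' @param dt_steps lag in samples (default 1, i.e. one TR).
#' @return scalar F with attribute `n_excluded`.
#' @export
information_cascade_flow <- function(field_hi, field_lo, dt_steps = 1L) {
  Rh <- field_R(field_hi)
  Rl <- field_R(field_lo)
  if (!all(dim(Rh) == dim(Rl))) stop_invalid("fields must have identical shapes")
  if (inherits(field_hi, "local_order_field") && inherits(field_lo, "local_order_field") &&
      field_hi$lambda <= field_lo$lambda) {
    stop_invalid("field_hi must be at the larger lambda")
  }
  T_ <- ncol(Rh)
  if (T_ - dt_steps < 3) stop_invalid("too few volumes for lag ", dt_steps)
  lead <- Rh[, (1 + dt_steps):T_, drop = FALSE]
  lag_ <- Rl[, 1:(T_ - dt_steps), drop = FALSE]
  vh <- apply(lead, 1L, stats::var)
  vl <- apply(lag_, 1L, stats::var)
  ok <- vh > 0 & vl > 0
  if (!any(ok)) stop_invalid("all nodes have zero temporal variance")
  r <- vapply(which(ok), function(n) stats::cor(lead[n, ], lag_[n, ]), numeric(1))
  out <- mean(r)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Information cascade
#'
#' The average of the information cascade flow over all adjacent scale
#' transitions: a single summary of cross-scale information propagation.
#'
#' @param F_values numeric vector of cascade-flow values, one per transition.
#' @return scalar mean.
#' @export
information_cascade <- function(F_values) {
  F_values <- as.numeric(F_values)
  if (length(F_values) < 1L) stop_invalid("need at least one scale transition")
  mean(F_values)
}

#' Log-log power-law fit of correlation versus distance
#'
#' Ordinary least squares of log(correlation) on log(distance), restricted
#' to pairs inside the inertial subrange `range_mm`. Pairs with
#' non-positive correlation (log undefined) are excluded and counted.
#'
#' @param r distances in mm.
#' @param corr correlations paired with `r`.
#' @param range_mm inertial subrange c(lo, hi) in mm.
#' @return list with slope `A`, intercept `B` (natural log), `n_used`,
#'   `n_excluded`.
#' @export
fit_loglog_slope <- function(r, corr, range_mm = c(10, 100)) {
  stopifnot(length(r) == length(corr))
  inside <- is.finite(r) & is.finite(corr) & r >= range_mm[1] & r <= range_mm[2]
  pos <- inside & corr > 0
  n_excluded <- sum(inside) - sum(pos)
  if (sum(pos) < 3) {
    stop_invalid("degenerate fit: fewer than 3 usable (positive-correlation) pairs in range")
  }
  fit <- stats::lm(log(corr[pos]) ~ log(r[pos]))
  list(A = unname(coef(fit)[2]), B = unname(coef(fit)[1]),
       n_used = sum(pos), n_excluded = n_excluded)
}

#' Information transfer across space at one scale
#'
#' The temporal correlation of the local order parameter between node pairs
#' decays with their Euclidean distance; its log-log slope inside the
#' inertial subrange quantifies how information travels across space at the
#' scale lambda. Pair correlations are averaged inside equal-width distance
#' bins (bin midpoints as r) before the fit, which stabilises it.
#'
#' @param field a `local_order_field`.
#' @param distances N x N distance matrix in mm.
#' @param bins number of equal-width distance bins in the subrange.
#' @param range_mm inertial subrange c(lo, hi) in mm.
#' @return list with `A` (slope), `B` (intercept), `n_used`, `n_excluded`,
#'   and `profile` (tibble of bin midpoints and mean correlations).
#' @export
information_transfer <- function(field, distances, bins = 50L, range_mm = c(10, 100)) {
  R <- field_R(field)
  distances <- as.matrix(distances)
  if (nrow(R) != nrow(distances)) stop_invalid("field and distances have different node counts")
  cormat <- suppressWarnings(stats::cor(t(R)))
  iu <- upper.tri(distances)
  d <- distances[iu]
  cc <- cormat[iu]
  keep <- is.finite(cc) & d >= range_mm[1] & d <= range_mm[2]
  binned <- bin_mean(d[keep], cc[keep], bins, range_mm)
  fit <- fit_loglog_slope(binned$r_mid, binned$value, range_mm)
  fit$profile <- binned
  fit
}

# equal-width binning of y over x in [range[1], range[2]]; empty bins dropped
bin_mean <- function(x, y, bins, range) {
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  agg <- tapply(y, idx, mean)
  counts <- tapply(y, idx, length)
  used <- as.integer(names(agg))
  tibble::tibble(bin = used, r_mid = mids[used],
                 value = as.numeric(agg), n_pairs = as.integer(counts))
}

#' Multi-scale turbulence summary of one subject
#'
#' Runs the full model-free pipeline on band-passed phases: local order
#' parameter at every scale of the grid, amplitude turbulence, node-level
#' metastability, network turbulence, information transfer, cascade flow
#' between adjacent scales, and the information cascade.
#'
#' @param phases a `phase_field` (see [extract_phases()]).
#' @param distances N x N distance matrix in mm.
#' @param lambdas scale grid (default [scale_grid()]).
#' @param rsn_labels optional per-node network labels.
#' @param transfer_range inertial subrange for information transfer, mm.
#' @param bins distance bins for information transfer.
#' @return object of class `turbulence_summary`: list of tibbles
#'   `global` (lambda, turbulence, transfer_slope, transfer_intercept),
#'   `cascade_flow` (lambda, flow — labelled by the larger scale of each
#'   transition), scalar `cascade`, `nlm` (lambda, node, value), and
#'   optionally `rsn` (lambda, network, turbulence).
#' @export
turbulence_summary <- function(phases, distances, lambdas = scale_grid(),
                               rsn_labels = NULL, transfer_range = c(10, 100),
                               bins = 50L) {
  fields <- lapply(lambdas, function(l) local_order(phases, distances, l))
  global <- purrr::map2_dfr(fields, lambdas, function(f, l) {
    tr <- tryCatch(information_transfer(f, distances, bins, transfer_range),
                   error = function(e) list(A = NA_real_, B = NA_real_))
    tibble::tibble(lambda = l, turbulence = amplitude_turbulence(f),
                   transfer_slope = tr$A, transfer_intercept = tr$B)
  })
  flow <- if (length(lambdas) > 1) {
    purrr::map_dbl(seq_along(lambdas)[-1], function(i) {
      as.numeric(information_cascade_flow(fields[[i]], fields[[i - 1]]))
    })
  } else numeric(0)
  cascade_flow <- tibble::tibble(lambda = lambdas[-1], flow = flow)
  nlm <- purrr::map2_dfr(fields, lambdas, function(f, l) {
    tibble::tibble(lambda = l, node = seq_len(nrow(f$R)), value = node_metastability(f))
  })
  out <- list(global = global, cascade_flow = cascade_flow,
              cascade = if (length(flow)) information_cascade(flow) else NA_real_,
              nlm = nlm)
  if (!is.null(rsn_labels)) {
    out$rsn <- purrr::map2_dfr(fields, lambdas, function(f, l) {
      dplyr::mutate(rsn_turbulence(f, rsn_labels), lambda = l, .before = 1)
    })
  }
  class(out) <- "turbulence_summary"
  out
}

#' @export
print.turbulence_summary <- function(x, ...) {
  cat("<turbulence_summary> ", nrow(x$global), " scales; cascade = ",
      signif(x$cascade, 4), "\n", sep = "")
  print(x$global)
  invisible(x)
}

#' @rdname turbulence_summary
#' @param x a `turbulence_summary`.
#' @param ... unused.
#' @export
tidy.turbulence_summary <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::pivot_longer(x$global, -"lambda", names_to = "measure"),
    dplyr::transmute(x$cascade_flow, lambda = .data$lambda,
                     measure = "cascade_flow", value = .data$flow)
  )
}

#' Plot amplitude turbulence across spatial scales
#'
#' @param object a `turbulence_summary`.
#' @param ... unused.
#' @return a ggplot of turbulence versus lambda.
#' @export
autoplot.turbulence_summary <- function(object, ...) {
  ggplot2::ggplot(object$global, ggplot2::aes(x = .data$lambda, y = .data$turbulence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda ~ (mm^-1)), y = "Amplitude turbulence D") +
    ggplot2::theme_minimal()
}
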