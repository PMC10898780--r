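#' Kolmogorov-Smirnov distance between two samples
#'
#' The supremum over x of the absolute difference between the two empirical
#' CDFs — used to compare node-level metastability distributions between
#' groups. Delegates to [stats::ks.test()] for the statistic.
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @return scalar KSD in \[0, 1\].
#' @export
ks_distance <- function(sample_a, sample_b) {
  if (length(sample_a) < 1L || length(sample_b) < 1L) {
    stop_invalid("both samples must be nonempty")
  }
  unname(suppressWarnings(stats::ks.test(sample_a, sample_b)$statistic))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (p_(i) * m / i with monotone
#' enforcement, capped at 1), delegated to [stats::p.adjust()]; the
#' original order is preserved.
#'
#' @param p_values numeric vector of raw p values in \[0, 1\].
#' @return adjusted p values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation with a two-sided p value
#'
#' Brain-behaviour association test: Pearson's r with the usual t-transform
#' p value, via [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return one-row tibble: method, estimate, statistic, p_value, n.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_invalid("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("undefined correlation: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(method = "pearson", estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 n = length(x))
}

#' Wilcoxon rank tests
#'
#' Between-group differences via the rank-sum test (unpaired) and
#' within-group differences via the signed-rank test (paired), delegated to
#' [stats::wilcox.test()]. Sample sizes below 5 trigger a warning that the
#' asymptotic p value is unreliable.
#'
#' @param sample_a,sample_b numeric samples (equal length when paired).
#' @param paired logical.
#' @param exact passed to [stats::wilcox.test()].
#' @return one-row tibble: method, statistic, p_value, n_a, n_b.
#' @export
rank_tests <- function(sample_a, sample_b, paired = FALSE, exact = NULL) {
  if (paired && length(sample_a) != length(sample_b)) {
    stop_invalid("paired samples must have equal length")
  }
  if (min(length(sample_a), length(sample_b)) < 5L) {
    warning("sample size < 5: p value unreliable", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, paired = paired,
                                            exact = exact))
  tibble::tibble(method = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(sample_a), n_b = length(sample_b))
}

#' Nodes in the top quantile of absolute differences, per network
#'
#' Selects the ceiling(q * N) nodes with the largest absolute node-level
#' differences (ties broken by node order) and tallies them per
#' resting-state network; the counts sum to the selected-set size.
#'
#' @param differences per-node absolute differences (e.g. of node-level
#'   metastability between groups).
#' @param q top quantile in (0, 1) (default 0.15).
#' @param rsn_labels per-node network labels.
#' @return tibble with columns network, n_nodes (zero-count networks
#'   included), with the selected node indices as attribute `selected`.
#' @export
top_quantile_nodes <- function(differences, q = 0.15, rsn_labels) {
  if (q <= 0 || q >= 1) stop_invalid("q must be in (0, 1)")
  if (length(differences) != length(rsn_labels)) {
    stop_invalid("labels must cover all nodes")
  }
  n <- length(differences)
  k <- ceiling(q * n)
  sel <- order(abs(differences), decreasing = TRUE)[seq_len(k)]
  labs <- as.character(rsn_labels)
  networks <- if (is.factor(rsn_labels)) levels(rsn_labels) else unique(labs)
  counts <- vapply(networks, function(net) sum(labs[sel] == net), integer(1))
  out <- tibble::tibble(network = networks, n_nodes = counts)
  attr(out, "selected") <- sort(sel)
  out
}

#' Factorial ANOVA / ANCOVA adapter
#'
#' Thin orchestration over [stats::aov()] for the group-level designs used
#' with the turbulence measures: between factors (e.g. group x lambda),
#' optional nuisance covariates (e.g. lesion volume), and an optional
#' subject identifier that adds a within-subject error stratum for
#' repeated-measures designs. The fitted formula is recorded in the output.
#'
#' @param data data frame in long format.
#' @param response name of the response column.
#' @param between character vector of factor column names.
#' @param covariates optional character vector of covariate column names.
#' @param id optional subject-identifier column for repeated measures.
#' @return tibble of ANOVA terms (term, df, sumsq, statistic, p_value, and
#'   stratum for repeated measures) with the formula as attribute
#'   `formula`.
#' @export
fit_group_anova <- function(data, response, between, covariates = NULL, id = NULL) {
  data <- as.data.frame(data)
  for (b in between) data[[b]] <- factor(data[[b]])
  rhs <- paste(c(covariates, paste(between, collapse = " * ")), collapse = " + ")
  if (!is.null(id)) {
    data[[id]] <- factor(data[[id]])
    rhs <- paste0(rhs, " + Error(", id, ")")
  }
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::aov(form, data = data)
  out <- if (inherits(fit, "aovlist")) {
    purrr::imap_dfr(fit[-1], function(stratum, nm) {
      dplyr::mutate(aov_table(stratum), stratum = nm, .before = 1)
    })
  } else {
    aov_table(fit)
  }
  attr(out, "formula") <- form
  out
}

aov_table <- function(fit) {
  s <- summary(fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(s)),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    statistic = if ("F value" %in% colnames(s)) s[["F value"]] else NA_real_,
    p_value = if ("Pr(>F)" %in% colnames(s)) s[["Pr(>F)"]] else NA_real_
  )
}
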