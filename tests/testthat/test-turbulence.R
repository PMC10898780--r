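test_that("local order parameter equals closed forms in degenerate regimes", {
  g <- tiny_geometry(10)
  ph <- matrix(0.7, 10, 20)                      # full synchrony
  f <- local_order(ph, g$distances, 0.03)
  expect_equal(f$R, matrix(1, 10, 20), tolerance = 1e-12)

  ph2 <- random_phases(10, 20, seed = 1)
  f2 <- local_order(ph2, g$distances, 100)        # kernel ~ identity
  expect_equal(f2$R, matrix(1, 10, 20), tolerance = 1e-6)

  # two antiphase nodes at distance r: R = (1 - e^(-lambda r)) / (1 + e^(-lambda r))
  d2 <- rbind(c(0, 10), c(10, 0))
  fab <- local_order(rbind(0, pi), d2, 0.03)
  expect_equal(fab$R[1, 1], (1 - exp(-0.3)) / (1 + exp(-0.3)), tolerance = 1e-12)
  expect_equal(fab$R[1, 1], 0.1489, tolerance = 1e-3)
})

test_that("local order parameter matches the straight-loop oracle and stays in [0,1]", {
  g <- tiny_geometry(15)
  ph <- random_phases(15, 25, seed = 2)
  for (lam in c(0.01, 0.06, 0.3)) {
    f <- local_order(ph, g$distances, lam)
    expect_equal(f$R, loop_local_order(ph, g$distances, lam), tolerance = 1e-10)
    expect_true(all(f$R >= 0 & f$R <= 1 + 1e-12))
  }
  bad <- ph
  bad[3, 7] <- NA
  expect_error(local_order(bad, g$distances, 0.03), "node 3, time 7")
})

test_that("amplitude turbulence is a pooled population SD, rotation-invariant", {
  R <- matrix(c(rep(0.2, 10), rep(0.4, 10)), 4, 5)
  expect_equal(amplitude_turbulence(R), 0.1, tolerance = 1e-12)
  expect_equal(amplitude_turbulence(matrix(0.5, 6, 9)), 0)

  set.seed(3)
  Rr <- matrix(runif(80), 8, 10)
  expect_equal(amplitude_turbulence(Rr), loop_pooled_sd(Rr), tolerance = 1e-12)

  # invariance under a global phase rotation of the underlying phases
  g <- tiny_geometry(12)
  ph <- random_phases(12, 30, seed = 4)
  d1 <- amplitude_turbulence(local_order(ph, g$distances, 0.05))
  d2 <- amplitude_turbulence(local_order(ph + 1.234, g$distances, 0.05))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("node-level metastability is the per-node temporal SD", {
  expect_equal(node_metastability(matrix(0.3, 5, 8)), rep(0, 5))
  expect_equal(node_metastability(matrix(c(0, 1), 1, 10)), 0.5)
  set.seed(5)
  R <- matrix(runif(60), 6, 10)
  expect_equal(node_metastability(R), loop_row_sd(R), tolerance = 1e-12)
})

test_that("network-level turbulence reduces to global D and matches masked oracle", {
  set.seed(6)
  R <- matrix(runif(100, 0.2, 0.9), 10, 10)
  labs <- rep("DMN", 10)
  one <- rsn_turbulence(R, labs)
  expect_equal(one$turbulence, amplitude_turbulence(R), tolerance = 1e-12)

  labs2 <- sample(c("VIS", "SM", "DAT"), 10, replace = TRUE)
  while (min(table(labs2)) < 2) labs2 <- sample(c("VIS", "SM", "DAT"), 10, replace = TRUE)
  tab <- rsn_turbulence(R, labs2)
  for (net in unique(labs2)) {
    expect_equal(tab$turbulence[tab$network == net],
                 loop_pooled_sd(R[labs2 == net, , drop = FALSE]), tolerance = 1e-10)
  }

  Rc <- R
  Rc[labs2 == "VIS", ] <- 0.5    # constant within one network
  expect_equal(rsn_turbulence(Rc, labs2)$turbulence[tab$network == "VIS"][1], 0)

  expect_warning(rsn_turbulence(R, c("A", rep("B", 9))), "< 2 nodes")
})

test_that("information cascade flow detects lagged (anti)correlation and nulls", {
  set.seed(7)
  base <- matrix(runif(20 * 51), 20, 51)
  # field_lo at time t equals field_hi at time t + 1: perfect lagged correlation
  hi <- structure(list(R = base[, 1:50], lambda = 0.04), class = "local_order_field")
  lo <- structure(list(R = base[, 2:51], lambda = 0.01), class = "local_order_field")
  expect_equal(as.numeric(information_cascade_flow(hi, lo, dt_steps = 1)), 1,
               tolerance = 1e-12)

  anti <- structure(list(R = -base[, 2:51], lambda = 0.01), class = "local_order_field")
  expect_equal(as.numeric(information_cascade_flow(hi, anti)), -1, tolerance = 1e-12)

  set.seed(8)
  a <- matrix(runif(5 * 1000), 5, 1000)
  b <- matrix(runif(5 * 1000), 5, 1000)
  expect_lt(abs(as.numeric(information_cascade_flow(a, b))), 0.1)

  expect_error(information_cascade_flow(a[, 1:4], b[, 1:4], dt_steps = 2), "few")
  expect_error(information_cascade_flow(lo, hi), "larger lambda")
})

test_that("information cascade averages flows across scale transitions", {
  expect_equal(information_cascade(c(0.2, 0.4)), 0.3)
  expect_equal(information_cascade(rep(0.17, 9)), 0.17)
  expect_length(scale_grid(), 10)
  expect_equal(length(scale_grid()) - 1, 9)   # default grid has 9 transitions
  expect_error(information_cascade(numeric(0)), "at least one")
})

test_that("log-log slope fit recovers analytic power laws exactly", {
  r <- c(10, 20, 40, 80)
  fit <- fit_loglog_slope(r, r^(-0.5), range_mm = c(5, 100))
  expect_equal(fit$A, -0.5, tolerance = 1e-12)

  fit2 <- fit_loglog_slope(r, rep(0.3, 4), range_mm = c(5, 100))
  expect_equal(fit2$A, 0, tolerance = 1e-12)

  fit3 <- fit_loglog_slope(r, 2 * r^(-1), range_mm = c(5, 100))
  expect_equal(fit3$A, -1, tolerance = 1e-12)
  expect_equal(fit3$B, log(2), tolerance = 1e-12)

  # non-positive correlations excluded and counted
  fit4 <- fit_loglog_slope(c(r, 50), c(r^(-0.5), -0.2), range_mm = c(5, 100))
  expect_equal(fit4$n_excluded, 1L)
  expect_equal(fit4$A, -0.5, tolerance = 1e-12)
  expect_error(fit_loglog_slope(c(10, 20), c(0.5, -0.1), c(5, 100)), "degenerate")
})

test_that("information transfer recovers a prescribed spatial decay exponent", {
  # Gaussian fields with correlation decaying as (r / r0)^(-0.8)
  set.seed(10)
  n <- 80
  pts <- matrix(runif(n * 3, 0, 120), n, 3)
  d <- pairwise_distances(pts)
  target <- pmin((pmax(d, 10) / 10)^(-0.8), 1)
  diag(target) <- 1
  ev <- eigen(target, symmetric = TRUE)
  cov_psd <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
  sdv <- sqrt(diag(cov_psd))
  cor_psd <- cov_psd / outer(sdv, sdv)
  L <- chol(cor_psd + diag(1e-9, n))
  X <- t(L) %*% matrix(rnorm(n * 3000), n, 3000)
  fit <- information_transfer(X, d, bins = 40, range_mm = c(12, 110))
  expect_equal(fit$A, -0.8, tolerance = 0.1)

  # a single shared time course: all pair correlations 1, slope 0
  shared <- matrix(rep(rnorm(50), each = n), n, 50)
  fit0 <- information_transfer(shared + 0, d, bins = 10, range_mm = c(12, 110))
  expect_equal(fit0$A, 0, tolerance = 1e-10)
})

test_that("binned information transfer equals the unbinned fit when bins isolate pairs", {
  pts <- rbind(c(0, 0, 0), c(30, 0, 0), c(70, 0, 0))
  d <- pairwise_distances(pts)   # pair distances 30, 40, 70 all distinct
  set.seed(11)
  X <- matrix(rnorm(3 * 400), 3, 400)
  X[2, ] <- X[1, ] + 0.5 * X[2, ]
  X[3, ] <- X[1, ] + 2.0 * X[3, ]
  fine <- information_transfer(X, d, bins = 400, range_mm = c(20, 80))
  cors <- cor(t(X))
  # compare against the unbinned pair values directly
  pair_d <- c(d[1, 2], d[1, 3], d[2, 3])
  pair_c <- c(cors[1, 2], cors[1, 3], cors[2, 3])
  direct <- fit_loglog_slope(pair_d, pair_c, range_mm = c(20, 80))
  # bin midpoints quantise r to the bin width, so agreement is to that order
  expect_equal(fine$A, direct$A, tolerance = 5e-3)
  expect_equal(fine$B, direct$B, tolerance = 5e-3)
})

test_that("mean local synchronisation grows with spatial averaging for random phases", {
  g <- make_geometry(150, seed = 12)
  means <- sapply(1:5, function(s) {
    ph <- random_phases(150, 40, seed = 100 + s)
    c(small = mean(local_order(ph, g$distances, 0.01)$R),
      large = mean(local_order(ph, g$distances, 0.30)$R))
  })
  # more spatial averaging (small lambda) cancels random phases -> smaller mean R
  expect_true(all(means["small", ] < means["large", ]))
})

test_that("turbulence summary runs the full model-free pipeline tidily", {
  g <- make_geometry(40, seed = 13)
  conn <- build_edr_connectome(g)
  sim <- simulate_hopf(conn, hopf_config(omega = random_omega(40), G = 1.2,
                                         n_volumes = 80, seed = 3))
  ph <- extract_phases(bandpass(sim))
  lam <- scale_grid()
  ts_sum <- turbulence_summary(ph, g$distances, lambdas = lam, rsn_labels = g$rsn_labels)
  expect_equal(nrow(ts_sum$global), 10)
  expect_true(all(is.finite(ts_sum$global$turbulence)))
  expect_true(all(ts_sum$global$turbulence >= 0))
  expect_equal(nrow(ts_sum$cascade_flow), 9)
  expect_equal(ts_sum$cascade, mean(ts_sum$cascade_flow$flow), tolerance = 1e-12)
  expect_true(all(ts_sum$nlm$value >= 0))
  expect_s3_class(tidy(ts_sum), "tbl_df")
  expect_s3_class(autoplot(ts_sum), "ggplot")
})
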