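test_that("synthetic lesion overlaps behave at the radius limits", {
  g <- tiny_geometry(30)
  tiny <- make_lesion_cohort(g, n_patients = 3, foci = 2, radius_mm = 1e-6, seed = 1)
  expect_lt(max(tiny$overlap), 1e-10)

  # one focus exactly on a node centroid with a huge radius covers it fully
  big <- make_lesion_cohort(g, n_patients = 2, foci = 1, radius_mm = 200, seed = 2)
  expect_true(all(big$overlap == 1))

  les <- make_lesion_cohort(make_geometry(200, seed = 4), n_patients = 10,
                            foci = 1, radius_mm = 15, seed = 5)
  expect_true(all(rowSums(les$overlap > 0) >= 1))
  expect_true(all(les$overlap >= 0 & les$overlap <= 1))
  expect_identical(les, make_lesion_cohort(make_geometry(200, seed = 4),
                                           n_patients = 10, foci = 1,
                                           radius_mm = 15, seed = 5))
  expect_error(make_lesion_cohort(g, 2, radius_mm = 0), "radius")
})

test_that("analytic sphere overlap matches a voxelised brute-force oracle", {
  g <- tiny_geometry(25, seed = 8)
  les <- make_lesion_cohort(g, n_patients = 1, foci = 1, radius_mm = 15, seed = 3)
  centre <- attr(les, "foci")$centres[[1]][1, ]
  node_r <- (3 * (8 * g$node_volumes) / (4 * pi))^(1 / 3)

  vox_fraction <- function(node) {
    # 1 mm voxel grid over the node sphere
    c0 <- g$centroids[node, ]
    r <- node_r[node]
    gr <- expand.grid(x = seq(c0[1] - r, c0[1] + r, by = 1),
                      y = seq(c0[2] - r, c0[2] + r, by = 1),
                      z = seq(c0[3] - r, c0[3] + r, by = 1))
    inside <- (gr$x - c0[1])^2 + (gr$y - c0[2])^2 + (gr$z - c0[3])^2 <= r^2
    lesioned <- (gr$x - centre[1])^2 + (gr$y - centre[2])^2 + (gr$z - centre[3])^2 <= 15^2
    sum(inside & lesioned) / sum(inside)
  }
  hit <- which(les$overlap[1, ] > 0.05 & les$overlap[1, ] < 0.95)
  for (node in utils::head(hit, 4)) {
    expect_equal(les$overlap[1, node], vox_fraction(node), tolerance = 0.08)
  }
})

test_that("voxel-grid overlap computes exact coverage ratios", {
  parc <- array(0L, c(8, 8, 4))
  parc[1:4, 1:4, ] <- 1L     # node 1: 64 voxels
  parc[5:8, 1:4, ] <- 2L     # node 2: 64 voxels
  lesion <- array(0L, c(8, 8, 4))
  lesion[1:2, 1:4, ] <- 1L   # half of node 1 in x -> 32 voxels

  tab <- compute_overlap(lesion, parc)
  expect_equal(tab$overlap[1, ], c(0.5, 0))

  expect_equal(compute_overlap(array(0L, c(8, 8, 4)), parc)$overlap[1, ], c(0, 0))

  exact <- array(0L, c(8, 8, 4))
  exact[parc == 2L] <- 1L
  expect_equal(compute_overlap(exact, parc)$overlap[1, ], c(0, 1))

  expect_error(compute_overlap(array(0L, c(4, 4, 4)), parc), "misaligned")
})

test_that("attack threshold is mean + k SD of pooled positive overlaps", {
  tab <- rbind(c(0.1, 0.1, 0, 0), c(0.1, 0, 0, 0.9))
  att <- nodes_to_attack(tab, k_sd = 1.5)
  # pooled positives {0.1, 0.1, 0.1, 0.9}: mean 0.3, population SD sqrt(0.12)
  expect_equal(att$threshold, 0.3 + 1.5 * sqrt(0.12), tolerance = 1e-12)
  expect_equal(att$per_patient[[1]], integer(0))
  expect_equal(att$per_patient[[2]], 4L)
  expect_equal(att$union, 4L)
  expect_equal(att$freq[4], 1L)

  # monotone in k: attack sets only shrink as the threshold rises
  set.seed(6)
  big <- matrix(runif(200) * (runif(200) < 0.3), 10, 20)
  sizes <- sapply(c(1.5, 2, 3, 4), function(k) {
    suppressWarnings(length(nodes_to_attack(big, k)$union))
  })
  expect_true(all(diff(sizes) <= 0))
  huge <- nodes_to_attack(big, 100)
  expect_equal(length(huge$union), 0)
  expect_warning(nodes_to_attack(matrix(0, 2, 3), 1.5), "zero")
})

test_that("lesion mask matrices implement binary and weighted disconnection", {
  att <- structure(list(per_patient = list(3L, integer(0)),
                        union = 3L, freq = c(0L, 0L, 1L, 0L),
                        threshold = 0.5, k_sd = 1.5, n_patients = 2L),
                   class = "attack_set")
  w <- lesion_mask_matrix(att, n_nodes = 4, mode = "weighted")
  expect_equal(w$node_factors, c(1, 1, 0.5, 1))
  expect_equal(w$M[3, ], c(0.5, 0.5, 0.5, 0.5))
  expect_equal(w$M[, 3], c(0.5, 0.5, 0.5, 0.5))
  expect_identical(w$M, t(w$M))

  b <- lesion_mask_matrix(att, n_nodes = 4, mode = "binary")
  expect_equal(b$M[3, ], rep(0, 4))
  expect_true(all(b$M[-3, -3] == 1))

  # a node lesioned in every patient collapses weighted onto binary
  att_all <- structure(list(per_patient = list(3L, 3L), union = 3L,
                            freq = c(0L, 0L, 2L, 0L), threshold = 0.5,
                            k_sd = 1.5, n_patients = 2L),
                       class = "attack_set")
  expect_equal(lesion_mask_matrix(att_all, 4, mode = "weighted")$M,
               lesion_mask_matrix(att_all, 4, mode = "binary")$M)

  none <- structure(list(per_patient = list(integer(0)), union = integer(0),
                         freq = rep(0L, 4), threshold = Inf, k_sd = 2,
                         n_patients = 1L), class = "attack_set")
  expect_true(all(lesion_mask_matrix(none, 4)$M == 1))

  # product combination penalises doubly attacked pairs at least as much as min
  att2 <- structure(list(per_patient = list(c(1L, 3L)), union = c(1L, 3L),
                         freq = c(1L, 0L, 1L, 0L), threshold = 0.5, k_sd = 1.5,
                         n_patients = 2L), class = "attack_set")
  mmin <- lesion_mask_matrix(att2, 4, mode = "weighted", pair_combine = "min")$M
  mprod <- lesion_mask_matrix(att2, 4, mode = "weighted", pair_combine = "product")$M
  expect_true(all(mprod <= mmin + 1e-15))
  expect_equal(mmin[1, 3], 0.5)
  expect_equal(mprod[1, 3], 0.25)
})

test_that("applying an attack only removes weight and zeroes binary rows", {
  g <- tiny_geometry(12)
  conn <- build_edr_connectome(g)
  les <- make_lesion_cohort(g, n_patients = 3, foci = 2, radius_mm = 20, seed = 9)
  att <- nodes_to_attack(les, 1.5)
  expect_gt(length(att$union), 0)

  wmask <- lesion_mask_matrix(att, 12, mode = "weighted")
  bmask <- lesion_mask_matrix(att, 12, mode = "binary")
  aw <- apply_attack(conn, wmask)
  ab <- apply_attack(conn, bmask)
  expect_equal(aw$provenance, "attacked")
  expect_true(all(aw$C <= conn$C + 1e-15))
  expect_true(all(ab$C <= aw$C + 1e-15))
  expect_true(all(ab$C[att$union, ] == 0))
  expect_true(all(ab$C[, att$union] == 0))
  expect_identical(aw$C, t(aw$C))

  ones <- lesion_mask_matrix(structure(list(per_patient = list(integer(0)),
                                            union = integer(0),
                                            freq = rep(0L, 12), threshold = Inf,
                                            k_sd = 1.5, n_patients = 1L),
                                       class = "attack_set"), 12)
  expect_equal(apply_attack(conn, ones)$C, conn$C)
})
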