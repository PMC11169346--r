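test_that("eta2 matches hand-computed values and its numerator identity", {
  set.seed(1)
  a <- rnorm(50)
  expect_equal(eta2(a, a), 1)
  expect_equal(eta2(a, 2 * a + 3), eta2(2 * a + 3, a))  # symmetric
  # hand arithmetic: a=(0,1), b=(1,0) -> eta2 = 0
  expect_equal(eta2(c(0, 1), c(1, 0)), 0)
  # numerator identity: sum((a-m)^2 + (b-m)^2) = 0.5 * ||a-b||^2
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    m <- (x + y) / 2
    expect_equal(sum((x - m)^2 + (y - m)^2), 0.5 * sum((x - y)^2))
  }
  # constant identical pair defined as 1
  expect_equal(eta2(rep(2, 5), rep(2, 5)), 1)
  # anti-related equal-mean maps share no variance: similarity 0; the
  # denominator exceeds the numerator by 2*sum((m - M)^2), so the
  # coefficient is bounded by [0, 1]
  expect_equal(eta2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 0)
  set.seed(3)
  for (i in 1:10) {
    e <- eta2(rnorm(20), rnorm(20))
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("the vectorised eta2 distance equals the scalar definition", {
  set.seed(2)
  maps <- matrix(rnorm(5 * 20), 5, 20)
  centroid <- rnorm(20)
  d <- aphasiamorph:::eta2_dist_rows(maps, centroid)
  for (i in 1:5)
    expect_equal(d[i], 1 - eta2(maps[i, ], centroid), tolerance = 1e-12)
})

test_that("eta2 k-means recovers planted archetypes and degenerate cases", {
  maps <- planted_maps(n_per = 12, k = 3, p = 40, noise = 0.02, seed = 4)
  km <- kmeans_eta2(maps, 3, replicates = 10, seed = 5)
  expect_equal(ari(km$labels, rep(1:3, each = 12)), 1.0)
  # k = n: every map its own cluster, zero objective
  small <- maps[1:6, ]
  km2 <- kmeans_eta2(small, 6, replicates = 3, seed = 1)
  expect_equal(sort(km2$labels), 1:6)
  expect_lt(km2$objective, 1e-12)
  # duplicated maps always co-cluster
  dup <- maps[rep(c(1, 13, 25), each = 4), ]
  km3 <- kmeans_eta2(dup, 3, replicates = 5, seed = 2)
  expect_equal(ari(km3$labels, rep(1:3, each = 4)), 1.0)
})

test_that("consensus matrices are symmetric, unit-diagonal, and binary for separated archetypes", {
  maps <- planted_maps(n_per = 10, k = 3, p = 40, noise = 0.01, seed = 6)
  M <- consensus_matrix(maps, 3, n_subsamples = 30, voxel_fraction = 0.6,
                        replicates = 5, seed = 7)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(1, 30))
  expect_true(all(M >= 0 & M <= 1))
  # perfectly separated archetypes: 1 within groups, 0 between
  truth <- rep(1:3, each = 10)
  same <- outer(truth, truth, `==`)
  expect_true(all(M[same] == 1))
  expect_true(all(M[!same] == 0))
  # a single subsample gives a binary matrix
  M1 <- consensus_matrix(maps, 3, n_subsamples = 1, replicates = 3, seed = 1)
  expect_true(all(M1 %in% c(0, 1)))
})

test_that("the dip statistic matches hand-solved small cases and screens modality", {
  # two well-separated atoms attain the maximal dip 1/4
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  expect_equal(dip_statistic(c(0, 0, 1, 1)), 0.25)
  # three equally spaced points attain the minimal dip 1/(2n)
  expect_equal(dip_statistic(c(0, 0.5, 1)), 1 / 6)
  # nonnegative and bounded
  set.seed(8)
  for (i in 1:10) {
    d <- dip_statistic(rnorm(50))
    expect_gte(d, 1 / 100)
    expect_lte(d, 0.25)
  }
  # sharp two-point mixture rejects unimodality
  bimodal <- c(rnorm(100, 0.05, 0.01), rnorm(100, 0.95, 0.01))
  expect_lt(dip_pvalue(bimodal, n_boot = 100, seed = 1)$p, 0.05)
  # uniform sample does not reject; p roughly uniform over seeds
  ps <- vapply(1:10, function(s) {
    set.seed(s + 50)
    dip_pvalue(runif(300), n_boot = 100, seed = s)$p
  }, numeric(1))
  expect_gt(median(ps), 0.2)
})

test_that("PAC counts strictly ambiguous consensus entries", {
  bin <- matrix(c(1, 0, 1, 0,
                  0, 1, 0, 1,
                  1, 0, 1, 0,
                  0, 1, 0, 1), 4, 4)
  expect_equal(pac(bin), 0)
  allmid <- matrix(0.5, 4, 4); diag(allmid) <- 1
  expect_equal(pac(allmid, 0.1, 0.9), 1)
  m <- diag(3)
  m[upper.tri(m)] <- c(0.05, 0.5, 0.95)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  expect_equal(pac(m, 0.1, 0.9), 1 / 3)
  expect_error(pac(bin, 0.9, 0.1), "u1")
})

test_that("model-order selection returns the most complex reliable solution", {
  st <- data.frame(k = c(3, 5, 7, 9),
                   dip_p = c(0.01, 0.01, 0.01, 0.5),
                   pac = c(0.0, 0.05, 0.08, 0.01))
  expect_equal(select_solution(st), 7)   # k=9 fails the dip screen
  st2 <- data.frame(k = 3, dip_p = 0.01, pac = 0.05)
  expect_equal(select_solution(st2), 3)
  st3 <- data.frame(k = c(3, 4), dip_p = c(0.5, 0.6), pac = c(0.3, 0.2))
  expect_warning(k <- select_solution(st3), "no solution")
  expect_equal(k, 4)
})

test_that("affinity propagation recovers blocks and honours the target k", {
  # block-diagonal 2-block consensus
  S <- matrix(0, 10, 10)
  S[1:5, 1:5] <- 1; S[6:10, 6:10] <- 1
  res <- extract_clusters_ap(S, target_k = 2)
  expect_equal(res$k, 2)
  expect_equal(ari(res$labels, rep(1:2, each = 5)), 1.0)
  expect_true(all(res$exemplar_ids[res$labels[res$exemplar_ids]] ==
                    res$exemplar_ids))
  # every exemplar belongs to its own cluster
  for (c in seq_along(res$exemplar_ids))
    expect_equal(res$labels[res$exemplar_ids[c]], c)
  # identity-like similarity with singleton-forcing target
  I5 <- diag(5)
  res2 <- extract_clusters_ap(I5, target_k = 5)
  expect_equal(res2$k, 5)
  expect_equal(sort(res2$exemplar_ids), 1:5)
})

test_that("the full subtyping pipeline recovers three planted archetypes", {
  maps <- planted_maps(n_per = 20, k = 3, p = 64, noise = 0.03, seed = 3)
  res <- run_subtyping(maps, k_range = 3:6, n_subsamples = 40,
                       voxel_fraction = 0.6, replicates = 5,
                       n_boot = 100, seed = 4)
  expect_equal(res$selected_k, 3)
  expect_lte(res$stats$pac[res$stats$k == 3], 0.05)
  expect_equal(ari(res$labels, rep(1:3, each = 20)), 1.0)
  # within-cluster mean eta2 exceeds between-cluster mean eta2
  sims <- matrix(NA_real_, 60, 60)
  for (i in 1:59) for (j in (i + 1):60)
    sims[i, j] <- eta2(maps[i, ], maps[j, ])
  same <- outer(res$labels, res$labels, `==`)[upper.tri(sims)]
  vals <- sims[upper.tri(sims)]
  expect_gt(mean(vals[same]), mean(vals[!same]))
})

test_that("added noise never decreases PAC at the true model order", {
  pacs <- vapply(c(0.01, 0.1, 0.3), function(noise) {
    out <- vapply(1:2, function(s) {
      maps <- planted_maps(n_per = 8, k = 3, p = 40, noise = noise, seed = s)
      M <- consensus_matrix(maps, 3, n_subsamples = 25, replicates = 3,
                            seed = s + 10)
      pac(M)
    }, numeric(1))
    mean(out)
  }, numeric(1))
  expect_true(all(diff(pacs) >= -1e-9))
})
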