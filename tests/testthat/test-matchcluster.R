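test_that("pooling stacks three loading vectors per trial with provenance", {
  mk <- function(n) lapply(seq_len(n), function(i)
    fake_decomp(sprintf("t%03d", i), matrix(rnorm(21), 7, 3)))
  set.seed(1)
  expect_equal(nrow(pool_loadings(mk(1))$vectors), 3)
  expect_equal(nrow(pool_loadings(mk(54))$vectors), 162)
  expect_equal(nrow(pool_loadings(mk(117))$vectors), 351)
  p <- pool_loadings(mk(2))
  expect_equal(p$provenance$rank, c(1, 2, 3, 1, 2, 3))

  mixed <- mk(2)
  mixed[[2]]$flavor <- "varimax"
  expect_error(pool_loadings(mixed), "mixed flavors")
})

make_clouds <- function(seed = 21, n_per = 30, sd = 0.02) {
  set.seed(seed)
  centers <- rbind(c(1, rep(0, 6)), c(0, 1, rep(0, 5)), c(0, 0, 1, rep(0, 4)))
  X <- do.call(rbind, lapply(1:3, function(j)
    rep(1, n_per) %o% centers[j, ] + matrix(rnorm(n_per * 7, sd = sd), n_per)))
  list(X = X, truth = rep(1:3, each = n_per), centers = centers)
}

test_that("k-means recovers well-separated clouds exactly and deterministically", {
  cl <- make_clouds()
  km <- kmeans3(cl$X, seed = 5)
  # same partition as ground truth (up to label permutation)
  expect_equal(length(unique(paste(km$labels, cl$truth))), 3)
  km2 <- kmeans3(cl$X, seed = 5)
  expect_identical(km$labels, km2$labels)

  # weighting invariance: duplicating every vector leaves centroids unchanged
  kmd <- kmeans3(rbind(cl$X, cl$X), seed = 5)
  sort_rows <- function(M) M[order(M[, 1], M[, 2]), ]
  expect_equal(sort_rows(kmd$centroids), sort_rows(km$centroids),
               tolerance = 1e-9)
})

test_that("k-means aligns loading-vector signs to the centroids", {
  cl <- make_clouds(seed = 22)
  flip <- rep(c(1, -1), length.out = nrow(cl$X))
  km <- kmeans3(cl$X * flip, seed = 5)
  expect_equal(length(unique(paste(km$labels, cl$truth))), 3)
  # after alignment all members point the same way as their centroid
  dots <- rowSums(km$vectors * km$centroids[km$labels, ])
  expect_true(all(dots > 0))
})

test_that("the farthest duplicate vector is shifted to the unassigned cluster", {
  fx <- conflict_fixture(c(1L, 1L, 3L), d_shared = c(0.2, 0.7, 0))
  a <- resolve_conflicts(fx$km, fx$prov)
  expect_equal(sort(a$labels), 1:3)
  expect_equal(a$labels, c(1L, 2L, 3L))     # the 0.7-distant vector moved
  expect_equal(a$conflicts$moved_rank, 2L)
  expect_equal(a$conflicts$from_cluster, 1L)
  expect_equal(a$conflicts$to_cluster, 2L)
  expect_equal(a$n_conflict_trials, 1L)
  # the recorded distance is to the new centroid
  expect_equal(a$distances[2],
               sqrt(sum((fx$km$vectors[2, ] - fx$km$centroids[2, ])^2)))
})

test_that("a clean assignment is untouched and resolution is idempotent", {
  fx <- conflict_fixture(c(1L, 2L, 3L))
  a <- resolve_conflicts(fx$km, fx$prov)
  expect_equal(a$labels, c(1L, 2L, 3L))
  expect_equal(nrow(a$conflicts), 0)
  expect_equal(a$n_conflict_trials, 0)
  a2 <- resolve_conflicts(list(labels = a$labels, vectors = a$vectors,
                               centroids = a$centroids,
                               distances = a$distances), fx$prov)
  expect_identical(a2$labels, a$labels)
  expect_identical(a2$distances, a$distances)
})

test_that("a triple conflict resolves farthest-first with rank tie-breaks", {
  fx <- conflict_fixture(c(2L, 2L, 2L), d_shared = c(0.5, 0.9, 0.1))
  a <- resolve_conflicts(fx$km, fx$prov)
  expect_equal(sort(a$labels), 1:3)
  expect_equal(nrow(a$conflicts), 2)
  # farthest (rank 2, d=0.9) moves first, then rank 1 (d=0.5)
  expect_equal(a$conflicts$moved_rank, c(2L, 1L))
  expect_equal(a$labels[3], 2L)             # nearest stays
  # exact-tie case: ties broken by within-trial rank
  fx2 <- conflict_fixture(c(2L, 2L, 2L), d_shared = c(0.5, 0.5, 0.5))
  a2 <- resolve_conflicts(fx2$km, fx2$prov)
  expect_equal(a2$conflicts$moved_rank, c(1L, 2L))
})

test_that("matching ignores within-trial rank order", {
  dec <- fixture_decomp_pca
  shuffled <- lapply(seq_along(dec), function(i) {
    d <- dec[[i]]
    set.seed(100 + i)
    d$loadings <- d$loadings[, sample(3)]
    d
  })
  a1 <- match_components(dec, "pca", seed = 3)
  a2 <- match_components(shuffled, "pca", seed = 3)
  cover <- function(a) {
    tab <- table(a$provenance$trial_id, a$labels)
    all(tab == 1)
  }
  expect_true(cover(a1))
  expect_true(cover(a2))
  expect_equal(a1$n_conflict_trials, a2$n_conflict_trials)
})

test_that("cluster relabelling names clusters after the dominant rank", {
  a <- match_components(fixture_decomp_pca, "pca", seed = 3)
  for (j in 1:3) {
    ranks <- a$provenance$rank[a$labels == j]
    expect_equal(as.integer(names(which.max(table(ranks)))), j)
  }
})

test_that("the stability census aggregates conflicts and distances", {
  dec_vm <- lapply(fixture_units, decompose_trial, flavor = "varimax")
  a_pca <- match_components(fixture_decomp_pca, "pca", seed = 3)
  a_vm <- match_components(dec_vm, "varimax", seed = 3)
  cs <- stability_census(a_pca, a_vm)
  n_trials <- length(fixture_units)
  expect_equal(nrow(cs$distance_table), 6 * n_trials)
  expect_equal(levels(cs$distance_table$component),
               c("PC1", "PC2", "PC3", "VM1", "VM2", "VM3"))
  expect_true(all(cs$conflicts >= 0))
  expect_equal(dim(cs$cluster_means$pca), c(3, 7))

  if (all(cs$conflicts == 0)) expect_equal(unname(cs$conflicts), c(0, 0))
})

test_that("ground-truth matching finds the best cluster-to-column permutation", {
  W <- make_synergy_model()$weights
  centroids <- t(W)[c(2, 3, 1), ] * c(1, -1, 1) * 0.8
  mt <- match_to_ground_truth(centroids, W)
  expect_equal(mt$permutation, c(2, 3, 1))
  expect_equal(mt$cosines, rep(1, 3), tolerance = 1e-9)
})
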