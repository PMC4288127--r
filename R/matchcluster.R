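#' Pool retained loading vectors across trials
#'
#' Stacks the three retained loading vectors of every decomposition into an
#' N x 7 matrix (N = 3 x trials), all mixed together without regard for each
#' vector's within-trial rank; the rank is kept as provenance only.
#'
#' @param decomps List of `emg_decomp` objects of one flavor.
#' @param flavor `"pca"` or `"varimax"`; all decompositions must match.
#' @return List with `vectors` (N x 7) and `provenance` (data frame with
#'   `trial_id`, `rank`, `flavor`).
#' @export
pool_loadings <- function(decomps, flavor = c("pca", "varimax")) {
  flavor <- match.arg(flavor)
  stopifnot(length(decomps) >= 1,
            all(vapply(decomps, inherits, TRUE, "emg_decomp")))
  flavors <- vapply(decomps, function(d) d$flavor, "")
  if (!all(flavors == flavor))
    stopf("mixed flavors in pool: expected all '%s'", flavor)
  ks <- vapply(decomps, function(d) ncol(d$loadings), 0L)
  if (!all(ks == 3L)) stopf("every decomposition must retain 3 components")
  vectors <- do.call(rbind, lapply(decomps, function(d) t(d$loadings)))
  ids <- vapply(seq_along(decomps), function(i) {
    id <- decomps[[i]]$trial_id
    if (is.null(id)) sprintf("trial%03d", i) else id
  }, "")
  provenance <- data.frame(trial_id = rep(ids, each = 3L),
                           rank = rep(1:3, length(decomps)),
                           flavor = flavor, stringsAsFactors = FALSE)
  list(vectors = vectors, provenance = provenance)
}

#' Sign-aware k-means with three clusters
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts by
#' within-cluster sum of squares. Because loading vectors carry an arbitrary
#' overall sign, sign alignment is interleaved with the assignment step: a
#' vector is flipped whenever its dot product with its nearest centroid is
#' negative (equivalently, each vector is assigned over both orientations).
#' Deterministic for a fixed seed.
#'
#' @param vectors N x p matrix (N >= 3).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 50).
#' @param max_iter Lloyd iterations per restart.
#' @return List with `labels` (length N), `centroids` (3 x p), `vectors`
#'   (sign-aligned copy), `distances` (to assigned centroid), `tot_withinss`.
#' @export
kmeans3 <- function(vectors, seed = 1L, n_init = 50, max_iter = 100) {
  X <- as.matrix(vectors)
  n <- nrow(X)
  if (n < 3) stopf("need at least 3 vectors")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      res <- kmeans3_once(X, max_iter)
      if (is.null(res)) next
      if (is.null(best) || res$tot_withinss < best$tot_withinss) best <- res
    }
  })
  if (is.null(best)) stopf("k-means failed: empty cluster in every restart")
  best
}

# one k-means++ initialization + Lloyd run with interleaved sign alignment
kmeans3_once <- function(X, max_iter) {
  n <- nrow(X)
  k <- 3L
  # k-means++ seeding on the sign-symmetrized distance
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(X, 1L, function(x) {
      min(apply(centers, 1L, function(c) {
        min(sum((x - c)^2), sum((x + c)^2))
      }))
    })
    if (sum(d2) == 0) {
      centers <- rbind(centers, X[sample.int(n, 1L), ])
    } else {
      centers <- rbind(centers, X[sample.int(n, 1L, prob = d2), ])
    }
  }
  Xa <- X
  labels <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    # orientation-aware assignment
    dpos <- outer_dist2(Xa, centers)
    dneg <- outer_dist2(-Xa, centers)
    flipped <- matrixStats_rowMins(dneg) < matrixStats_rowMins(dpos)
    Xa[flipped, ] <- -Xa[flipped, , drop = FALSE]
    d2 <- outer_dist2(Xa, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    if (any(tabulate(new_labels, k) == 0L)) return(NULL)
    if (all(new_labels == labels) && !any(flipped)) break
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(Xa[labels == j, , drop = FALSE])
  }
  d2 <- outer_dist2(Xa, centers)
  distances <- sqrt(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = centers, vectors = Xa,
       distances = distances, tot_withinss = sum(distances^2))
}

outer_dist2 <- function(X, C) {
  # squared Euclidean distances, N x k
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, "+") - 2 * X %*% t(C)
}

matrixStats_rowMins <- function(M) do.call(pmin, as.data.frame(M))

#' Resolve duplicate cluster assignments within trials
#'
#' A trial whose three loading vectors do not cover the three clusters has a
#' *conflict*: two (or three) vectors share a cluster. Following the
#' matching rule, the vector with the highest distance from the shared
#' cluster's centroid is shifted to a cluster left unassigned for that
#' trial; when all three vectors share one cluster the farthest moves first
#' (to the nearest of the empty clusters), then the rule is re-applied. Ties
#' are broken by within-trial rank, then trial order, so resolution is fully
#' deterministic. Reassigned distances are recomputed to the new centroid.
#'
#' @param km Result of [kmeans3()].
#' @param provenance Provenance data frame from [pool_loadings()] (exactly 3
#'   vectors per trial).
#' @return A `synergy_clusters` object: `vectors`, `provenance`, `labels`
#'   (resolved), `labels_raw`, `centroids`, `distances`, `conflicts` (data
#'   frame log), `n_conflict_trials`, `seed`, `n_init` when available.
#' @export
resolve_conflicts <- function(km, provenance) {
  labels <- km$labels
  X <- km$vectors
  C <- km$centroids
  n <- length(labels)
  stopifnot(nrow(provenance) == n)
  if (any(table(provenance$trial_id) != 3L))
    stopf("each trial must contribute exactly 3 vectors")
  distances <- km$distances
  conflicts <- list()
  trial_ids <- unique(provenance$trial_id)
  for (tid in trial_ids) {
    idx <- which(provenance$trial_id == tid)
    idx <- idx[order(provenance$rank[idx])]
    guard <- 0L
    while (length(unique(labels[idx])) < 3L && guard < 3L) {
      guard <- guard + 1L
      counts <- tabulate(labels[idx], 3L)
      empty <- which(counts == 0L)
      shared <- which(counts >= 2L)[1L]
      members <- idx[labels[idx] == shared]
      # farthest from the shared centroid moves; ties by within-trial rank
      d_shared <- sqrt(colSums((t(X[members, , drop = FALSE]) - C[shared, ])^2))
      mover <- members[order(-d_shared, provenance$rank[members])][1L]
      # destination: nearest empty cluster
      d_empty <- vapply(empty, function(j) sum((X[mover, ] - C[j, ])^2), 0)
      dest <- empty[which.min(d_empty)]
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        trial_id = tid, flavor = provenance$flavor[mover],
        moved_rank = provenance$rank[mover], from_cluster = shared,
        to_cluster = dest,
        distance = sqrt(sum((X[mover, ] - C[dest, ])^2)),
        stringsAsFactors = FALSE)
      labels[mover] <- dest
      distances[mover] <- sqrt(sum((X[mover, ] - C[dest, ])^2))
    }
  }
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(trial_id = character(), flavor = character(),
               moved_rank = integer(), from_cluster = integer(),
               to_cluster = integer(), distance = numeric(),
               stringsAsFactors = FALSE)
  structure(list(vectors = X, provenance = provenance, labels = labels,
                 labels_raw = km$labels, centroids = C,
                 distances = distances, conflicts = conflicts,
                 n_conflict_trials = length(unique(conflicts$trial_id)),
                 seed = km$seed, n_init = km$n_init),
            class = "synergy_clusters")
}

#' Match components across trials
#'
#' The full matching stage: pool the retained loading vectors of all trials,
#' cluster them into three groups with [kmeans3()], relabel the clusters so
#' that cluster j is the one dominated by within-trial rank-j vectors
#' (PC1/PC2/PC3 in the usual naming), and apply the conflict-reassignment
#' rule so every trial ends up contributing exactly one vector to each
#' cluster.
#'
#' @param decomps List of `emg_decomp` objects.
#' @param flavor `"pca"` or `"varimax"`.
#' @param seed,n_init Passed to [kmeans3()].
#' @return A `synergy_clusters` object (see [resolve_conflicts()]).
#' @export
match_components <- function(decomps, flavor = c("pca", "varimax"),
                             seed = 1L, n_init = 50) {
  flavor <- match.arg(flavor)
  pooled <- pool_loadings(decomps, flavor)
  km <- kmeans3(pooled$vectors, seed = seed, n_init = n_init)
  km <- relabel_by_rank(km, pooled$provenance)
  km$seed <- seed
  km$n_init <- n_init
  resolve_conflicts(km, pooled$provenance)
}

# relabel clusters so cluster j mostly holds within-trial rank-j vectors
relabel_by_rank <- function(km, provenance) {
  mean_rank <- vapply(1:3, function(j)
    mean(provenance$rank[km$labels == j]), 0)
  ord <- order(mean_rank)           # ord[new] = old
  remap <- match(1:3, ord)          # remap[old] = new
  km$labels <- remap[km$labels]
  km$centroids <- km$centroids[ord, , drop = FALSE]
  km
}

#' @export
print.synergy_clusters <- function(x, ...) {
  cat(sprintf("Synergy cluster assignment (%s): %d vectors, %d trials\n",
              x$provenance$flavor[1L], nrow(x$vectors),
              length(unique(x$provenance$trial_id))))
  cat(sprintf("  conflicts: %d trial(s), %d reassignment(s)\n",
              x$n_conflict_trials, nrow(x$conflicts)))
  cat("Cluster centroids:\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' Stability census comparing PCA and varimax matchings
#'
#' Gathers, for a PCA and a varimax assignment over the same trials, the
#' number of movements whose vectors were not unambiguously clustered
#' (conflicts), the centroid-distance of every vector labelled by a 6-level
#' component factor (PC1-PC3, VM1-VM3) for the downstream dispersion ANOVA,
#' and the per-cluster mean loading vectors with their across-trial
#' dispersions.
#'
#' @param assign_pca,assign_vm `synergy_clusters` objects over identical
#'   trials.
#' @return List with `conflicts` (named counts of conflicted movements),
#'   `reassignments`, `distance_table` (data frame: `component`, `distance`,
#'   `trial_id`; 6 x trials rows), `cluster_means`, `cluster_sds`.
#' @export
stability_census <- function(assign_pca, assign_vm) {
  stopifnot(inherits(assign_pca, "synergy_clusters"),
            inherits(assign_vm, "synergy_clusters"))
  t1 <- sort(unique(assign_pca$provenance$trial_id))
  t2 <- sort(unique(assign_vm$provenance$trial_id))
  if (!identical(t1, t2)) stopf("assignments cover different trials")
  tab <- function(a, prefix) data.frame(
    component = paste0(prefix, a$labels),
    distance = a$distances,
    trial_id = a$provenance$trial_id, stringsAsFactors = FALSE)
  distance_table <- rbind(tab(assign_pca, "PC"), tab(assign_vm, "VM"))
  distance_table$component <- factor(distance_table$component,
                                     levels = c(paste0("PC", 1:3),
                                                paste0("VM", 1:3)))
  cl_stats <- function(a) {
    means <- t(vapply(1:3, function(j)
      colMeans(a$vectors[a$labels == j, , drop = FALSE]),
      numeric(ncol(a$vectors))))
    sds <- t(vapply(1:3, function(j)
      apply(a$vectors[a$labels == j, , drop = FALSE], 2L, stats::sd),
      numeric(ncol(a$vectors))))
    list(means = means, sds = sds)
  }
  s_pca <- cl_stats(assign_pca)
  s_vm <- cl_stats(assign_vm)
  list(conflicts = c(pca = assign_pca$n_conflict_trials,
                     varimax = assign_vm$n_conflict_trials),
       reassignments = c(pca = nrow(assign_pca$conflicts),
                         varimax = nrow(assign_vm$conflicts)),
       distance_table = distance_table,
       cluster_means = list(pca = s_pca$means, varimax = s_vm$means),
       cluster_sds = list(pca = s_pca$sds, varimax = s_vm$sds))
}

#' Match cluster centroids to ground-truth synergy columns
#'
#' Finds the cluster-to-column permutation maximizing the total absolute
#' cosine similarity between centroids and the columns of a ground-truth
#' weight matrix (sign is immaterial for loading directions).
#'
#' @param centroids 3 x 7 centroid matrix.
#' @param weights 7 x 3 ground-truth weight matrix.
#' @return List with `permutation` (column index for each centroid) and
#'   `cosines` (absolute cosine for each matched pair).
#' @export
match_to_ground_truth <- function(centroids, weights) {
  cosmat <- abs(centroids %*% weights) /
    outer(sqrt(rowSums(centroids^2)), sqrt(colSums(weights^2)))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p) sum(cosmat[cbind(1:3, p)]), 0)
  best <- perms[[which.max(scores)]]
  list(permutation = best, cosines = cosmat[cbind(1:3, best)])
}
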