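# K-means clustering of per-gene expression patterns across replicate-level
# samples, per-cluster correlation coefficients, correlation-preserving
# greedy merging, and the sample-wise randomization control that bounds the
# cluster coherence achievable by chance.

as_profile_matrix <- function(m) {
  if (inherits(m, "ExpressionMatrix")) m <- m$values
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  m
}

# squared Euclidean distances between all rows of x and rows of centers
sq_dist <- function(x, centers) {
  d <- matrix(rowSums(x^2), nrow(x), nrow(centers)) -
    2 * x %*% t(centers) +
    matrix(rowSums(centers^2), nrow(x), nrow(centers), byrow = TRUE)
  pmax(d, 0)
}

# One Lloyd run from a given set of initial centers. Empty clusters are
# re-seeded from the point currently farthest from its assigned center.
lloyd_once <- function(x, centers, max_iter) {
  assign_prev <- rep(0L, nrow(x))
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- sq_dist(x, centers)
    assign <- max.col(-d, ties.method = "first")
    mind <- d[cbind(seq_len(nrow(x)), assign)]
    empty <- setdiff(seq_len(nrow(centers)), unique(assign))
    for (j in empty) {
      far <- which.max(mind)
      centers[j, ] <- x[far, ]
      assign[far] <- j
      mind[far] <- 0
    }
    trace <- c(trace, sum(mind))
    if (identical(assign, assign_prev) || iter >= max_iter) break
    assign_prev <- assign
    for (j in unique(assign))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  list(assignment = assign, centers = centers, objective = sum(mind),
       iterations = iter, trace = trace)
}

#' K-means clustering of mean-centered expression profiles
#'
#' Each gene's profile across samples is mean-centered (no variance
#' scaling), then Lloyd's K-means with Euclidean distance is run to
#' convergence (unchanged assignments) or `max_iter`. Initial centers are
#' `k` distinct genes sampled without replacement under `seed`; `n_init`
#' restarts are performed and the solution with the lowest total
#' within-cluster squared distance is kept. Results are deterministic given
#' the seed. Empty clusters are re-seeded from the farthest point.
#'
#' @param m Genes x samples numeric matrix (or an `ExpressionMatrix`),
#'   already restricted to the genes to cluster.
#' @param k Number of clusters (<= number of genes).
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return A `ClusterSet`: list with `assignment` (named integer vector),
#'   `centers` (k x samples), `sizes`, `objective`, `objective_trace` (of
#'   the winning restart), `iterations`, `profiles` (the centered matrix),
#'   `k`, `seed`.
#' @export
kmeans_cluster <- function(m, k, seed = 1L, n_init = 10, max_iter = 100) {
  x <- as_profile_matrix(m)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  if (ncol(x) < 2) stop("need >= 2 samples")
  xc <- x - rowMeans(x)
  best <- NULL
  withr::with_seed(seed, {
    for (rep in seq_len(n_init)) {
      init <- xc[sample.int(nrow(xc), k), , drop = FALSE]
      fit <- lloyd_once(xc, init, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  assignment <- stats::setNames(best$assignment, rownames(x))
  structure(list(assignment = assignment, centers = best$centers,
                 sizes = tabulate(best$assignment, nbins = k),
                 objective = best$objective,
                 objective_trace = best$trace,
                 iterations = best$iterations,
                 profiles = xc, k = as.integer(k), seed = as.integer(seed)),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d genes in %d clusters (objective %.4g, %d iterations)\n",
              length(x$assignment), x$k, x$objective, x$iterations))
  invisible(x)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Per-cluster correlation coefficients
#'
#' For each cluster, the mean over member genes of the Pearson correlation
#' between the gene's centered profile and the cluster's mean profile.
#' Singleton clusters get coefficient 1. A zero-variance member profile, or
#' a flat cluster mean profile, contributes correlation 0 and flags the
#' cluster as degenerate.
#'
#' @param cs A `ClusterSet`.
#' @return `data.frame` with columns `cluster`, `n`, `coefficient`,
#'   `min_coefficient`, `degenerate`.
#' @export
cluster_correlations <- function(cs) {
  stopifnot(inherits(cs, "ClusterSet"))
  ids <- sort(unique(cs$assignment))
  rows <- lapply(ids, function(j) {
    members <- cs$profiles[cs$assignment == j, , drop = FALSE]
    if (nrow(members) == 1)
      return(data.frame(cluster = j, n = 1L, coefficient = 1,
                        min_coefficient = 1, degenerate = FALSE))
    meanprof <- colMeans(members)
    cors <- apply(members, 1, safe_cor, b = meanprof)
    degenerate <- anyNA(cors)
    cors[is.na(cors)] <- 0
    data.frame(cluster = j, n = nrow(members), coefficient = mean(cors),
               min_coefficient = min(cors), degenerate = degenerate)
  })
  do.call(rbind, rows)
}

# coefficient of the cluster formed by the given member rows
pooled_coefficient <- function(profiles, members) {
  sub <- profiles[members, , drop = FALSE]
  if (nrow(sub) == 1) return(1)
  meanprof <- colMeans(sub)
  cors <- apply(sub, 1, safe_cor, b = meanprof)
  cors[is.na(cors)] <- 0
  mean(cors)
}

#' Merge clusters with similar patterns but different magnitudes
#'
#' Greedy merging: cluster mean profiles are standardized (centered, unit
#' variance) and the pair with the highest correlation at or above
#' `merge_threshold` is tentatively merged; the merge is committed only if
#' neither original cluster's correlation coefficient drops by more than
#' `max_drop` in the merged cluster, otherwise the pair is marked
#' ineligible. Repeats until no eligible pair remains. Gene membership is
#' never changed, only the partition is coarsened.
#'
#' @param cs A `ClusterSet`.
#' @param merge_threshold Minimum correlation between standardized mean
#'   profiles for a candidate merge (default 0.9).
#' @param max_drop Maximum tolerated drop of a cluster's coefficient upon
#'   merging (default 0.03).
#' @return A new `ClusterSet` (cluster ids are the smaller of each merged
#'   pair's ids) with a `merge_log` data.frame recording committed merges.
#' @export
merge_clusters <- function(cs, merge_threshold = 0.9, max_drop = 0.03) {
  stopifnot(inherits(cs, "ClusterSet"))
  assignment <- cs$assignment
  profiles <- cs$profiles
  coefs <- cluster_correlations(cs)
  coef_of <- stats::setNames(coefs$coefficient, coefs$cluster)
  blocked <- character(0)
  log <- list()
  repeat {
    ids <- sort(unique(assignment))
    if (length(ids) < 2) break
    centers <- t(vapply(ids, function(j)
      colMeans(profiles[assignment == j, , drop = FALSE]),
      numeric(ncol(profiles))))
    sds <- apply(centers, 1, stats::sd)
    std <- (centers - rowMeans(centers)) / ifelse(sds == 0, NA, sds)
    cc <- suppressWarnings(stats::cor(t(std)))
    cc[!is.finite(cc)] <- -Inf
    cc[lower.tri(cc, diag = TRUE)] <- -Inf
    for (key in blocked) {
      ij <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
      sel <- match(ij, ids)
      if (!anyNA(sel)) cc[sel[1], sel[2]] <- -Inf
    }
    if (max(cc) < merge_threshold) break
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    a <- ids[top[1]]; b <- ids[top[2]]
    members <- assignment %in% c(a, b)
    merged_coef <- pooled_coefficient(profiles, members)
    drop_a <- coef_of[[as.character(a)]] - merged_coef
    drop_b <- coef_of[[as.character(b)]] - merged_coef
    if (max(drop_a, drop_b) > max_drop) {
      blocked <- c(blocked, paste(a, b, sep = ":"))
      next
    }
    assignment[assignment == b] <- a
    coef_of[[as.character(a)]] <- merged_coef
    log[[length(log) + 1]] <- data.frame(kept = a, absorbed = b,
                                         coefficient = merged_coef,
                                         max_drop = max(drop_a, drop_b))
  }
  ids <- sort(unique(assignment))
  centers <- t(vapply(ids, function(j)
    colMeans(profiles[assignment == j, , drop = FALSE]),
    numeric(ncol(profiles))))
  rownames(centers) <- ids
  out <- cs
  out$assignment <- assignment
  out$centers <- centers
  out$sizes <- as.integer(table(factor(assignment, levels = ids)))
  out$merge_log <- if (length(log)) do.call(rbind, log) else
    data.frame(kept = integer(0), absorbed = integer(0),
               coefficient = numeric(0), max_drop = numeric(0))
  out
}

#' Randomization control for cluster coherence
#'
#' For each replicate: the values of each sample (column) are permuted
#' across genes, the permuted matrix is re-clustered with the same `k`, and
#' the per-cluster correlation coefficients are recorded. The resulting null
#' distribution bounds the coherence achievable by chance; on structured
#' data the real coefficients should exceed its maximum.
#'
#' @param m Genes x samples matrix (or `ExpressionMatrix`) as given to
#'   [kmeans_cluster()] (linear scale; centering happens inside).
#' @param k Number of clusters.
#' @param n_reps Number of randomization replicates (>= 1).
#' @param seed Integer seed.
#' @param n_init Restarts per replicate (default 3; the null needs no
#'   polishing).
#' @return List with `coefficients` (all replicates pooled), `per_rep`
#'   (list of per-replicate coefficient vectors), and `max`. Singleton
#'   clusters are excluded: their coefficient is 1 by convention and carries
#'   no information about chance coherence.
#' @export
randomization_control <- function(m, k, n_reps = 10, seed = 1L, n_init = 3) {
  x <- as_profile_matrix(m)
  if (n_reps < 1) stop("n_reps must be >= 1 (an empty null is not usable)")
  per_rep <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      perm <- apply(x, 2, sample)
      rownames(perm) <- rownames(x)
      sub_seed <- sample.int(.Machine$integer.max, 1)
      cs <- kmeans_cluster(perm, k, seed = sub_seed, n_init = n_init)
      co <- cluster_correlations(cs)
      co$coefficient[co$n >= 2]
    })
  })
  all_coefs <- unlist(per_rep)
  list(coefficients = all_coefs, per_rep = per_rep, max = max(all_coefs))
}
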