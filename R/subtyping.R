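#' Eta-squared similarity between two maps
#'
#' Point-by-point similarity accounting for scaling and offset:
#' `eta2 = 1 - sum((a-m)^2 + (b-m)^2) / sum((a-M)^2 + (b-M)^2)` with
#' `m_i = (a_i+b_i)/2` and `M` the mean of all `m_i`. Identical maps give 1,
#' maps sharing no variance give 0; the denominator equals the numerator
#' plus `2 * sum((m - M)^2)`, so the coefficient lies in \[0, 1\]. The
#' numerator equals `0.5 * ||a - b||^2`. A constant identical pair (zero
#' denominator) is defined as similarity 1.
#'
#' @param map_a,map_b Equal-length numeric vectors (>= 2 entries).
#' @return Scalar similarity (at most 1).
#' @export
eta2 <- function(map_a, map_b) {
  a <- as.vector(map_a); b <- as.vector(map_b)
  stopifnot(length(a) == length(b), length(a) >= 2)
  m <- (a + b) / 2
  mbar <- mean(m)
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - mbar)^2 + (b - mbar)^2)
  if (den < 1e-300) return(1)
  1 - num / den
}

# 1 - eta2 distances from every row of `maps` to one centroid, vectorised.
eta2_dist_rows <- function(maps, centroid, row_sums = NULL, row_sq = NULL) {
  p <- length(centroid)
  if (is.null(row_sums)) row_sums <- rowSums(maps)
  if (is.null(row_sq)) row_sq <- rowSums(maps^2)
  sc <- sum(centroid); sc2 <- sum(centroid^2)
  num <- 0.5 * (row_sq + sc2 - 2 * as.vector(maps %*% centroid))
  mbar <- (row_sums / p + sc / p) / 2
  den <- row_sq - 2 * mbar * row_sums + p * mbar^2 +
    sc2 - 2 * mbar * sc + p * mbar^2
  d <- ifelse(den < 1e-300, 0, num / pmax(den, 1e-300))
  pmax(d, 0)
}

#' k-means clustering under the 1 - eta2 distance
#'
#' Lloyd iterations with member-mean centroids and assignment by smallest
#' `1 - eta2`; k-means++ seeding uses the same distance; the best of
#' `replicates` restarts by total within-cluster distance is returned. Empty
#' clusters are re-seeded from the point farthest from its centroid.
#'
#' @param maps n x p matrix, one map per row.
#' @param k Number of clusters (`n >= k`).
#' @param replicates Restarts (the subtyping default is 250).
#' @param seed Integer seed (omit to use the current RNG state).
#' @param max_iter Lloyd iteration cap per restart.
#' @return List with `labels`, `centroids`, `objective`.
#' @export
kmeans_eta2 <- function(maps, k, replicates = 250, seed = NULL,
                        max_iter = 100) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(maps)
  stopifnot(n >= k)
  row_sums <- rowSums(maps); row_sq <- rowSums(maps^2)
  best <- list(objective = Inf)
  for (rep_i in seq_len(replicates)) {
    centroids <- kmeanspp_seed(maps, k, row_sums, row_sq)
    labels <- integer(n)
    obj <- Inf
    for (it in seq_len(max_iter)) {
      D <- vapply(seq_len(k), function(c)
        eta2_dist_rows(maps, centroids[c, ], row_sums, row_sq), numeric(n))
      D <- matrix(D, n, k)
      new_labels <- max.col(-D)
      mind <- D[cbind(seq_len(n), new_labels)]
      # re-seed empty clusters from the farthest point
      for (c in seq_len(k)) {
        if (!any(new_labels == c)) {
          far <- which.max(mind)
          new_labels[far] <- c
          mind[far] <- 0
        }
      }
      new_obj <- sum(mind)
      if (identical(new_labels, labels) || new_obj >= obj - 1e-12) {
        if (new_obj < obj) { labels <- new_labels; obj <- new_obj }
        break
      }
      labels <- new_labels; obj <- new_obj
      for (c in seq_len(k))
        centroids[c, ] <- colMeans(maps[labels == c, , drop = FALSE])
    }
    if (obj < best$objective)
      best <- list(labels = labels, centroids = centroids, objective = obj)
  }
  best
}

# k-means++ seeding under the 1 - eta2 distance.
kmeanspp_seed <- function(maps, k, row_sums, row_sq) {
  n <- nrow(maps)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  mind <- eta2_dist_rows(maps, maps[centers[1], ], row_sums, row_sq)
  for (c in seq_len(k - 1)) {
    w <- pmax(mind, 0)
    if (sum(w) < 1e-300) w <- rep(1, n)
    centers[c + 1] <- sample.int(n, 1, prob = w)
    d_new <- eta2_dist_rows(maps, maps[centers[c + 1], ], row_sums, row_sq)
    mind <- pmin(mind, d_new)
  }
  maps[centers, , drop = FALSE]
}

#' Consensus matrix by voxel subsampling
#'
#' Repeatedly clusters all subjects on a random fraction of voxels and
#' records, for each subject pair, the proportion of subsamples in which
#' the pair lands in the same cluster. Because subsampling is over voxels
#' (features), every pair appears in every iteration.
#'
#' @param maps n x p matrix of (normalized) saliency maps.
#' @param k Number of clusters per subsample.
#' @param n_subsamples Subsampling iterations (study default 1000).
#' @param voxel_fraction Fraction of voxels drawn per iteration (0.6).
#' @param replicates k-means restarts per iteration (study default 250).
#' @param seed Integer seed.
#' @return n x n symmetric consensus matrix with unit diagonal.
#' @export
consensus_matrix <- function(maps, k, n_subsamples = 1000,
                             voxel_fraction = 0.6, replicates = 250,
                             seed = 1L) {
  set.seed(seed)
  n <- nrow(maps); p <- ncol(maps)
  m <- max(1, round(voxel_fraction * p))
  counts <- matrix(0, n, n)
  for (it in seq_len(n_subsamples)) {
    vox <- sample.int(p, m)
    km <- kmeans_eta2(maps[, vox, drop = FALSE], k, replicates = replicates)
    same <- outer(km$labels, km$labels, `==`)
    counts <- counts + same
  }
  M <- counts / n_subsamples
  diag(M) <- 1
  M
}

#' Hartigan's dip statistic and bootstrap p-value
#'
#' `dip_statistic` computes the dip of a sample: half the largest gap
#' between the greatest convex minorant and least concave majorant of the
#' empirical cdf over the candidate modal interval, combined with the
#' largest deviations of the empirical cdf from the two fits outside it.
#' `dip_pvalue` calibrates it by Monte-Carlo simulation under the uniform
#' null (the dip is location/scale invariant). In the subtyping pipeline the
#' tested sample is the upper triangle of a consensus matrix: a solution
#' whose consensus values fail to reject unimodality shows no consensus
#' structure and is screened out.
#'
#' @param x Numeric sample (>= 4 values for a meaningful test).
#' @return `dip_statistic`: the dip (in \[1/(2n), 0.25\]).
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2) return(0)
  if (x[1] == x[n]) return(1 / (2 * n))
  # collapse ties: gcm uses the lowest pre-jump value, lcm the highest value
  ux <- unique(x)
  lo_ix <- match(ux, x)                     # first occurrence
  hi_ix <- length(x) - match(ux, rev(x)) + 1  # last occurrence
  y_g <- (lo_ix - 1) / n   # F just below the atom
  y_l <- hi_ix / n         # F at the atom
  m <- length(ux)
  lo <- 1; hi <- m; D <- 0
  for (guard in seq_len(m + 2)) {
    g <- hull_touch(ux, y_g, lo, hi, lower = TRUE)
    l <- hull_touch(ux, y_l, lo, hi, lower = FALSE)
    cand <- sort(unique(c(g, l)))
    gapv <- pl_eval(ux[l], y_l[l], ux[cand]) - pl_eval(ux[g], y_g[g], ux[cand])
    d <- max(gapv)
    if (d <= D) break
    j <- cand[which.max(gapv)]
    ig <- max(g[g <= j]); ih <- min(l[l >= j])
    seg_l <- lo:ig
    d_l <- max(y_l[seg_l] - pl_eval(ux[g], y_g[g], ux[seg_l]))
    seg_u <- ih:hi
    d_u <- max(pl_eval(ux[l], y_l[l], ux[seg_u]) - y_g[seg_u])
    D <- max(D, d_l, d_u)
    if (ig == lo && ih == hi) break
    lo <- ig; hi <- ih
  }
  D / 2
}

# Touch indices (within [lo, hi]) of the convex minorant (lower = TRUE) or
# concave majorant of the points (x_i, y_i), by monotone-chain hull scan.
hull_touch <- function(x, y, lo, hi, lower = TRUE) {
  ix <- lo:hi
  keep <- integer(0)
  for (i in ix) {
    while (length(keep) >= 2) {
      a <- keep[length(keep) - 1]; b <- keep[length(keep)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      ok <- if (lower) cross > 0 else cross < 0
      if (ok) break
      keep <- keep[-length(keep)]
    }
    keep <- c(keep, i)
  }
  keep
}

# Piecewise-linear interpolation through knots (xs, ys) evaluated at x0
# (x0 within [min(xs), max(xs)]).
pl_eval <- function(xs, ys, x0) {
  if (length(xs) == 1) return(rep(ys, length(x0)))
  stats::approx(xs, ys, xout = x0, rule = 2, ties = "ordered")$y
}

#' @rdname dip_statistic
#' @param n_boot Monte-Carlo draws under the uniform null.
#' @param seed Integer seed.
#' @return `dip_pvalue`: list with `dip`, `p`.
#' @export
dip_pvalue <- function(x, n_boot = 200, seed = 1L) {
  if (length(x) < 4) stop("dip_pvalue: need at least 4 values")
  obs <- dip_statistic(x)
  set.seed(seed)
  null <- vapply(seq_len(n_boot), function(i)
    dip_statistic(runif(length(x))), numeric(1))
  list(dip = obs, p = (sum(null >= obs) + 1) / (n_boot + 1))
}

#' Proportion of ambiguously clustered pairs
#'
#' Fraction of upper-triangle consensus entries strictly inside `(u1, u2)`;
#' lower is more reliable (0 means every pair is always or never
#' co-clustered).
#'
#' @param consensus n x n consensus matrix.
#' @param u1,u2 Ambiguity bounds, `0 <= u1 < u2 <= 1` (defaults 0.1, 0.9).
#' @return Proportion in \[0, 1\].
#' @export
pac <- function(consensus, u1 = 0.1, u2 = 0.9) {
  stopifnot(u1 >= 0, u1 < u2, u2 <= 1)
  v <- consensus[upper.tri(consensus)]
  mean(v > u1 & v < u2)
}

#' Select the clustering model order
#'
#' Among solutions whose consensus distribution rejects unimodality
#' (`dip_p < alpha`) and whose PAC is at most `pac_threshold`, the most
#' complex (largest k) is selected. If none qualify, the k with minimal PAC
#' is returned with a warning.
#'
#' @param per_k_stats data.frame with columns `k`, `dip_p`, `pac`.
#' @param pac_threshold Maximum PAC for a reliable solution (default 0.1).
#' @param alpha Dip-test screening level (default 0.05).
#' @return Selected k.
#' @export
select_solution <- function(per_k_stats, pac_threshold = 0.1, alpha = 0.05) {
  if (nrow(per_k_stats) == 0) stop("select_solution: empty stats")
  ok <- per_k_stats$dip_p < alpha & per_k_stats$pac <= pac_threshold
  if (any(ok)) return(max(per_k_stats$k[ok]))
  warning("select_solution: no solution passed screening; returning minimal-PAC k")
  per_k_stats$k[which.min(per_k_stats$pac)]
}

#' Affinity propagation on a consensus (similarity) matrix
#'
#' Message-passing exemplar clustering with damping. When `target_k` is
#' given, the shared preference is adjusted by bisection until the number of
#' clusters matches (bounded iterations; the nearest achievable solution is
#' returned with a warning otherwise). Exemplars are refined to the member
#' maximizing within-cluster similarity.
#'
#' @param similarity Square symmetric similarity matrix (e.g. consensus).
#' @param target_k Desired number of clusters, or `NULL` for AP's natural
#'   count at the median-similarity preference.
#' @param damping Message damping in \[0.5, 1) (default 0.7).
#' @param max_iter,conv_iter Iteration cap and required stable iterations.
#' @return List with `labels`, `exemplar_ids`, `k`, `preference`.
#' @export
extract_clusters_ap <- function(similarity, target_k = NULL, damping = 0.7,
                                max_iter = 500, conv_iter = 50) {
  stopifnot(nrow(similarity) == ncol(similarity))
  off <- similarity[row(similarity) != col(similarity)]
  pref <- median(off)
  if (is.null(target_k)) return(ap_run(similarity, pref, damping, max_iter, conv_iter))
  p_lo <- min(off) - (max(off) - min(off)) * 2 - 1
  p_hi <- max(off) + (max(off) - min(off)) * 2 + 1
  best <- NULL
  for (it in 1:30) {
    pref <- (p_lo + p_hi) / 2
    res <- ap_run(similarity, pref, damping, max_iter, conv_iter)
    if (is.null(best) || abs(res$k - target_k) < abs(best$k - target_k))
      best <- res
    if (res$k == target_k) return(res)
    if (res$k < target_k) p_lo <- pref else p_hi <- pref
  }
  warning(sprintf(
    "extract_clusters_ap: bisection reached k=%d (target %d)", best$k, target_k))
  best
}

ap_run <- function(S, preference, damping, max_iter, conv_iter) {
  n <- nrow(S)
  S2 <- S + matrix(rnorm(n * n, 0, 1e-12), n, n)  # tiny jitter breaks ties
  diag(S2) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L
  last_ex <- integer(0)
  for (it in seq_len(max_iter)) {
    AS <- A + S2
    # top-two maxima per row
    mx1_ix <- max.col(AS)
    mx1 <- AS[cbind(seq_len(n), mx1_ix)]
    AS2 <- AS
    AS2[cbind(seq_len(n), mx1_ix)] <- -Inf
    mx2 <- AS2[cbind(seq_len(n), max.col(AS2))]
    Rnew <- S2 - mx1
    Rnew[cbind(seq_len(n), mx1_ix)] <- S2[cbind(seq_len(n), mx1_ix)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- cs - diag(R)  # sum of clamped off-diagonal responsibilities
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last_ex) && length(ex) > 0) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= conv_iter) break
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0) ex <- which.max(diag(R) + diag(A))
  labels <- vapply(seq_len(n), function(i) {
    if (i %in% ex) match(i, ex)
    else which.max(S[i, ex])
  }, integer(1))
  # refine exemplars: member maximizing within-cluster similarity
  exemplars <- vapply(seq_along(ex), function(c) {
    members <- which(labels == c)
    if (length(members) == 1) return(members)
    members[which.max(rowSums(S[members, members, drop = FALSE]))]
  }, integer(1))
  list(labels = labels, exemplar_ids = exemplars, k = length(ex),
       preference = preference)
}

#' Consensus-clustering subtyping of saliency maps
#'
#' Full model-order search: for each k, build the voxel-subsampled consensus
#' matrix, screen by the dip test of its consensus distribution, score
#' reliability by PAC, select the most complex reliable solution, and
#' extract its clusters and exemplars by affinity propagation. Severe and
#' nonsevere predictions should be clustered in separate calls.
#'
#' @param maps n x p matrix of normalized saliency maps.
#' @param k_range Candidate cluster counts (study default 3:30).
#' @param n_subsamples,voxel_fraction,replicates See [consensus_matrix()].
#' @param pac_threshold,alpha See [select_solution()].
#' @param u1,u2 PAC ambiguity bounds.
#' @param n_boot Dip bootstrap draws.
#' @param seed Integer seed.
#' @return A `consensus_run`: per-k statistics, consensus matrices, the
#'   selected k, labels and exemplar ids.
#' @export
run_subtyping <- function(maps, k_range = 3:30, n_subsamples = 1000,
                          voxel_fraction = 0.6, replicates = 250,
                          pac_threshold = 0.1, alpha = 0.05,
                          u1 = 0.1, u2 = 0.9, n_boot = 200, seed = 1L) {
  stopifnot(nrow(maps) > max(k_range))
  consensus <- list()
  stats <- data.frame(k = k_range, dip = NA_real_, dip_p = NA_real_,
                      pac = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    M <- consensus_matrix(maps, k, n_subsamples, voxel_fraction,
                          replicates, seed = derive_seed(seed, k))
    consensus[[as.character(k)]] <- M
    v <- M[upper.tri(M)]
    dp <- dip_pvalue(v, n_boot = n_boot, seed = derive_seed(seed, 1000 + k))
    stats$dip[i] <- dp$dip
    stats$dip_p[i] <- dp$p
    stats$pac[i] <- pac(M, u1, u2)
  }
  selected_k <- select_solution(stats, pac_threshold, alpha)
  apres <- extract_clusters_ap(consensus[[as.character(selected_k)]],
                               target_k = selected_k)
  structure(list(stats = stats, consensus = consensus,
                 selected_k = selected_k, labels = apres$labels,
                 exemplar_ids = apres$exemplar_ids, seed = seed),
            class = "consensus_run")
}
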