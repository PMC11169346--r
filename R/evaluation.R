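#' Binary classification metrics (severe = positive class)
#'
#' Precision, recall (severe-class accuracy), nonsevere-class accuracy,
#' balanced accuracy (mean of the two class accuracies) and F1 (harmonic
#' mean of precision and recall; defined as 0 when the model makes no
#' positive predictions). Intended to be applied to predictions concatenated
#' across outer folds.
#'
#' @param y_true,y_pred Label vectors (`"severe"`/`"nonsevere"`, factors, or
#'   0/1 with 1 = severe).
#' @return List with `precision`, `recall`, `nonsevere_accuracy`,
#'   `balanced_accuracy`, `f1` and the confusion counts.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("compute_metrics: empty input")
  stopifnot(length(y_true) == length(y_pred))
  t_pos <- labels_to_y(y_true) == 2
  p_pos <- labels_to_y(y_pred) == 2
  tp <- sum(t_pos & p_pos); fp <- sum(!t_pos & p_pos)
  fn <- sum(t_pos & !p_pos); tn <- sum(!t_pos & !p_pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  nonsev <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall,
       nonsevere_accuracy = nonsev,
       balanced_accuracy = (recall + nonsev) / 2,
       f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Permutation test of a cross-validated score
#'
#' Permutes the class labels `m` times, reruns the full model-building
#' procedure through `runner` on each permutation (partitions are rebuilt
#' for the permuted labels so stratification follows them), and reports
#' `p = (#\{null >= observed\} + 1) / (m + 1)` - the observed result counts
#' as a member of its own null distribution, so p is never below
#' `1/(m + 1)`.
#'
#' @param runner Function taking a label vector and returning a scalar score
#'   (e.g. F1 from a full cross-validated fit).
#' @param labels Observed label vector.
#' @param m Number of permutations (the study used 500).
#' @param seed Integer seed for the permutations.
#' @return List with `observed`, `null` (length m) and `p`.
#' @export
permutation_test <- function(runner, labels, m = 500, seed = 1L) {
  if (m < 1) stop("permutation_test: m must be >= 1")
  observed <- runner(labels)
  set.seed(seed)
  null <- vapply(seq_len(m), function(i) runner(sample(labels)), numeric(1))
  p <- (sum(null >= observed) + 1) / (m + 1)
  list(observed = observed, null = null, p = p)
}

#' Paired comparison of model scores across repeats
#'
#' Paired t-test on per-repeat score differences (same partitions for both
#' models) with Cohen's d = mean(diff)/sd(diff). Zero-variance differences
#' are flagged (`degenerate = TRUE`, infinite t).
#'
#' @param scores_a,scores_b Equal-length per-repeat score vectors.
#' @return List with `t`, `df`, `p`, `cohens_d`, `degenerate`.
#' @export
paired_comparison <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  n <- length(d)
  s <- sd(d)
  if (!is.finite(s) || s < 1e-300) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = if (mean(d) == 0) 1 else 0,
                cohens_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / s, degenerate = FALSE)
}

#' Decode a saliency map against topic meta-analysis maps
#'
#' Pearson-correlates the (lesion-masked) saliency map with each topic map
#' and retains topics passing both the correlation threshold and the
#' Bonferroni-corrected p-value criterion (`p * n_topics < alpha`).
#'
#' @param exemplar_map 3D saliency array (an exemplar subject's map).
#' @param topic_maps Named list of 3D arrays on the same grid.
#' @param lesion_mask Optional binary array; in-lesion voxels are excluded
#'   from both vectors before correlating.
#' @param r_threshold Minimum correlation (default 0.2).
#' @param alpha Family-wise error target (default 1e-4).
#' @return data.frame with `topic`, `r`, `p`, `p_bonferroni`, `retained`.
#' @export
decode_topics <- function(exemplar_map, topic_maps, lesion_mask = NULL,
                          r_threshold = 0.2, alpha = 1e-4) {
  stopifnot(length(topic_maps) > 0)
  keep <- if (is.null(lesion_mask)) rep(TRUE, length(exemplar_map))
          else as.vector(lesion_mask == 0)
  v <- as.vector(exemplar_map)[keep]
  if (sd(v) < 1e-300) stop("decode_topics: saliency map is constant off-lesion")
  n_topics <- length(topic_maps)
  rows <- lapply(seq_len(n_topics), function(i) {
    tv <- as.vector(topic_maps[[i]])[keep]
    if (sd(tv) < 1e-300) return(data.frame(topic = names(topic_maps)[i],
                                           r = NA_real_, p = NA_real_))
    ct <- cor.test(v, tv)
    data.frame(topic = names(topic_maps)[i], r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * n_topics, 1)
  out$retained <- !is.na(out$r) & out$r > r_threshold &
    out$p * n_topics < alpha
  out
}
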