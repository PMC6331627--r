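entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Best binary cut of x w.r.t. class entropy, with the Fayyad-Irani MDL
# acceptance rule. Entropies of every candidate prefix/suffix are computed
# at once from cumulative class counts.
best_cut <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  cand <- which(xs[-1] > xs[-n])        # between distinct values
  if (length(cand) == 0L) return(NULL)
  classes <- unique(ys)
  cum <- vapply(classes, function(cl) cumsum(ys == cl),
                numeric(n))             # n x k cumulative counts
  tot <- cum[n, ]
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  ent_of <- function(counts, size) {    # rows of counts / size
    p <- counts / size
    -rowSums(plogp(p))
  }
  left <- cum[cand, , drop = FALSE]
  right <- rep(tot, each = length(cand)) - left
  dim(right) <- dim(left)
  n1 <- cand; n2 <- n - cand
  e1 <- ent_of(left, n1); e2 <- ent_of(right, n2)
  ent <- ent_of(matrix(tot, 1), n)[1]
  gain <- ent - (n1 / n) * e1 - (n2 / n) * e2
  b <- which.max(gain)
  k <- sum(tot > 0)
  k1 <- rowSums(left[b, , drop = FALSE] > 0)
  k2 <- rowSums(right[b, , drop = FALSE] > 0)
  delta <- log2(3^k - 2) - (k * ent - k1 * e1[b] - k2 * e2[b])
  if (gain[b] <= (log2(n - 1) + delta) / n) return(NULL)
  i <- cand[b]
  (xs[i] + xs[i + 1]) / 2
}

mdl_cuts <- function(x, y) {
  cut <- best_cut(x, y)
  if (is.null(cut)) return(numeric(0))
  left <- x < cut
  sort(c(mdl_cuts(x[left], y[left]), cut, mdl_cuts(x[!left], y[!left])))
}

#' Supervised discretization of a continuous feature
#'
#' Recursive entropy-based binning with the MDL stopping criterion
#' (Fayyad--Irani): cut points are accepted only when the class-entropy gain
#' exceeds the MDL coding cost. When no cut is accepted the feature falls
#' back to 10 equal-frequency bins; a constant feature yields a single bin.
#'
#' @param values Numeric feature vector.
#' @param labels Class labels, same length.
#' @param fallback_bins Equal-frequency bins used when MDL accepts no split.
#' @return Integer bin assignment (1-based), with attribute `"cuts"` holding
#'   the accepted cut values (empty when the fallback was used).
#' @export
discretize_feature <- function(values, labels, fallback_bins = 10L) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  if (length(unique(values)) == 1L)
    return(structure(rep(1L, length(values)), cuts = numeric(0)))
  cuts <- mdl_cuts(values, labels)
  if (length(cuts) == 0L) {
    br <- unique(stats::quantile(values, probs = seq(0, 1,
                                                     length.out = fallback_bins + 1L),
                                 names = FALSE))
    bins <- findInterval(values, br, all.inside = TRUE)
    return(structure(as.integer(bins), cuts = numeric(0)))
  }
  structure(findInterval(values, cuts) + 1L, cuts = cuts)
}

#' Information gain of a discrete feature with respect to the class
#'
#' `IG = H(class) - sum_v p(t = v) H(class | t = v)`, in bits.
#'
#' @param t Discrete (binned) feature vector.
#' @param labels Class labels, same length.
#' @export
information_gain <- function(t, labels) {
  if (length(t) == 0L) stop("empty input")
  stopifnot(length(t) == length(labels))
  h <- entropy_bits(labels)
  cond <- 0
  for (v in unique(t)) {
    sel <- t == v
    cond <- cond + mean(sel) * entropy_bits(labels[sel])
  }
  h - cond
}

#' Gain ratio of a discrete feature
#'
#' Information gain divided by the intrinsic (split) entropy of the feature's
#' bin distribution; 0 when the feature has a single bin.
#'
#' @inheritParams information_gain
#' @export
gain_ratio <- function(t, labels) {
  h_split <- entropy_bits(t)
  if (h_split == 0) return(0)
  information_gain(t, labels) / h_split
}

#' Feature-class correlation score
#'
#' Absolute Pearson correlation between the raw feature and the 0/1 class
#' code; 0 for a zero-variance feature.
#'
#' @param values Numeric feature vector.
#' @param labels Class labels (two classes).
#' @export
correlation_score <- function(values, labels) {
  y <- as.numeric(factor(labels)) - 1
  if (stats::sd(values) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(values, y))
}

#' Score all features by the three filter criteria
#'
#' Each feature column is MDL-discretized and scored by information gain and
#' gain ratio; the correlation score uses the raw values. Returns a ranking
#' table laid out one row per feature.
#'
#' @param X Numeric feature matrix (rows = instances, named columns).
#' @param labels Class labels.
#' @return data.frame with columns `feature`, `information_gain`,
#'   `gain_ratio`, `correlation` and the per-criterion ranks.
#' @export
rank_features <- function(X, labels) {
  X <- as.matrix(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(X)))
  ig <- gr <- co <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    t <- discretize_feature(X[, j], labels)
    ig[j] <- information_gain(t, labels)
    gr[j] <- gain_ratio(t, labels)
    co[j] <- correlation_score(X[, j], labels)
  }
  rank_of <- function(s) match(seq_along(s), order(-s, seq_along(s)))
  data.frame(feature = nm, information_gain = ig, gain_ratio = gr,
             correlation = co,
             rank_information_gain = rank_of(ig),
             rank_gain_ratio = rank_of(gr),
             rank_correlation = rank_of(co))
}

#' Keep the top-k features by score
#'
#' Descending stable sort; ties are broken by the lower canonical feature
#' index. Default k = 13 of the 16 texture features.
#'
#' @param scores Named (or plain) numeric vector, one score per feature.
#' @param k Number of features to retain.
#' @return Integer indices of the retained features, best first, with names
#'   when `scores` is named.
#' @export
rank_and_select <- function(scores, k = 13L) {
  if (k > length(scores)) stop("k exceeds the number of features")
  ord <- order(-scores, seq_along(scores))
  sel <- ord[seq_len(k)]
  if (!is.null(names(scores))) names(sel) <- names(scores)[sel]
  sel
}

#' Select features on a training matrix
#'
#' Convenience wrapper: scores with [rank_features()] and keeps the top `k`
#' by the chosen criterion.
#'
#' @inheritParams rank_features
#' @param k Number of features to keep (default 13).
#' @param criterion `"information_gain"` (default), `"gain_ratio"` or
#'   `"correlation"`.
#' @return Integer column indices of the selected features.
#' @export
select_features <- function(X, labels, k = 13L,
                            criterion = c("information_gain", "gain_ratio",
                                          "correlation")) {
  criterion <- match.arg(criterion)
  tab <- rank_features(X, labels)
  rank_and_select(stats::setNames(tab[[criterion]], tab$feature), k)
}
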