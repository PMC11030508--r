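# Feature-selection rankings: mRMR, neighborhood component analysis and
# chi-square, plus their top-k consensus.

# Equal-frequency discretization into at most `bins` levels (rank-based,
# deterministic; a constant feature collapses to one level).
equal_freq_bins <- function(x, bins = 8) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(r / length(x) * bins)
  match(b, sort(unique(b)))
}

# Mutual information (nats) between two discrete vectors.
mutual_information <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  pos <- tab > 0
  sum(tab[pos] * log(tab[pos] / outer(pa, pb)[pos]))
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy forward selection maximizing mutual information with the class
#' label minus the mean mutual information with already-selected features
#' (the MID "difference" scheme; `scheme = "miq"` uses the quotient).
#' Features are discretized into equal-frequency bins for the mutual
#' information estimates.  Ties break lexicographically on feature name,
#' so the ordering is deterministic.
#'
#' @param x data.frame or matrix of features (columns named).
#' @param y class labels (>= 2 classes).
#' @param k number of features to rank (default: all).
#' @param bins discretization bins.
#' @param scheme `"mid"` (difference) or `"miq"` (quotient).
#' @return object of class `feature_ranking`: data.frame with `feature`,
#'   `score` (greedy objective at selection), `relevance`, `rank`.
#' @export
rank_mrmr <- function(x, y, k = ncol(x), bins = 8, scheme = c("mid", "miq")) {
  scheme <- match.arg(scheme)
  x <- as.data.frame(x)
  y <- as.factor(y)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  k <- min(k, ncol(x))
  disc <- lapply(x, equal_freq_bins, bins = bins)
  rel <- vapply(disc, mutual_information, b = y, numeric(1))
  feats <- names(x)
  ord <- order(-rel, feats)
  selected <- character(0); scores <- numeric(0)
  red <- matrix(NA_real_, ncol(x), ncol(x), dimnames = list(feats, feats))
  remaining <- feats[ord]
  while (length(selected) < k) {
    if (!length(selected)) {
      pick <- remaining[1]
      sc <- rel[pick]
    } else {
      for (f in remaining) for (s in selected)
        if (is.na(red[f, s]))
          red[f, s] <- red[s, f] <- mutual_information(disc[[f]], disc[[s]])
      mred <- vapply(remaining, function(f) mean(red[f, selected]), numeric(1))
      obj <- if (scheme == "mid") rel[remaining] - mred
             else rel[remaining] / (mred + .Machine$double.eps)
      pick <- remaining[order(-obj, remaining)][1]
      sc <- obj[[pick]]
    }
    selected <- c(selected, pick)
    scores <- c(scores, sc)
    remaining <- setdiff(remaining, pick)
  }
  structure(data.frame(feature = selected, score = scores,
                       relevance = as.numeric(rel[selected]),
                       rank = seq_along(selected)),
            class = c("feature_ranking", "data.frame"),
            method = "mrmr")
}

#' Rank features by neighborhood component analysis (NCA)
#'
#' Learns per-feature weights maximizing the expected leave-one-out
#' accuracy of a stochastic nearest-neighbor classifier with the weighted
#' L1 metric \eqn{d_w(x_i,x_j)=\sum_r w_r^2 |x_{ir}-x_{jr}|}, with L2
#' regularization \eqn{\lambda \sum_r w_r^2}.  Features are standardized
#' first, so raw feature scaling does not affect the ranking.  Optimized
#' by gradient ascent with step halving; if the iteration cap is hit the
#' best iterate is returned with `converged = FALSE`.
#'
#' @param x feature data.frame/matrix.
#' @param y class labels.
#' @param lambda regularization (default 1/n).
#' @param max_iter,tol gradient ascent controls.
#' @param step0 initial step size.
#' @return `feature_ranking` data.frame with `feature`, `score` (the
#'   squared weight), `rank`; attributes `converged`, `iterations`,
#'   `objective`.
#' @export
rank_nca <- function(x, y, lambda = NULL, max_iter = 100, tol = 1e-6,
                     step0 = 0.5) {
  x <- as.matrix(as.data.frame(x))
  y <- as.factor(y)
  n <- nrow(x); d <- ncol(x)
  if (is.null(lambda)) lambda <- 1 / n
  mu <- colMeans(x); sg <- apply(x, 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  # per-feature absolute difference arrays
  D <- array(0, c(n, n, d))
  for (r in seq_len(d)) D[, , r] <- abs(outer(xs[, r], xs[, r], "-"))
  same <- outer(y, y, "==") * 1
  diag(same) <- 0
  w <- rep(1, d)
  objective <- function(w) {
    dist <- matrix(0, n, n)
    for (r in seq_len(d)) dist <- dist + w[r]^2 * D[, , r]
    K <- exp(-(dist - apply(dist + diag(Inf, n), 1, min)))
    diag(K) <- 0
    rs <- rowSums(K)
    rs[rs == 0] <- 1
    p <- K / rs
    pi_ <- rowSums(p * same)
    list(F = mean(pi_) - lambda * sum(w^2), p = p, pi = pi_)
  }
  grad <- function(w, ob) {
    g <- numeric(d)
    for (r in seq_len(d)) {
      Dr <- D[, , r]
      g[r] <- 2 * w[r] * (mean(ob$pi * rowSums(ob$p * Dr) -
                                 rowSums(ob$p * same * Dr)) - lambda)
    }
    g
  }
  ob <- objective(w)
  best_w <- w; best_F <- ob$F
  step <- step0; it <- 0; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    g <- grad(w, ob)
    w_new <- w + step * g
    ob_new <- objective(w_new)
    if (ob_new$F > ob$F) {
      if (abs(ob_new$F - ob$F) < tol) { converged <- TRUE }
      w <- w_new; ob <- ob_new
      step <- step * 1.1
      if (ob$F > best_F) { best_F <- ob$F; best_w <- w }
      if (converged) break
    } else {
      step <- step / 2
      if (step < 1e-8) { converged <- TRUE; break }
    }
  }
  wt <- best_w^2
  names(wt) <- colnames(x)
  ordn <- order(-wt, names(wt))
  structure(data.frame(feature = names(wt)[ordn], score = as.numeric(wt[ordn]),
                       rank = seq_along(wt)),
            class = c("feature_ranking", "data.frame"),
            method = "nca", converged = converged, iterations = it,
            objective = best_F)
}

#' Rank features by chi-square association with the class
#'
#' Each feature is discretized into equal-frequency bins; the chi-square
#' statistic of the bin-by-class contingency table is the score (a
#' constant feature scores 0).  Ranking is by decreasing statistic with
#' lexicographic tie-break.
#'
#' @param x feature data.frame/matrix.
#' @param y class labels.
#' @param bins discretization bins.
#' @return `feature_ranking` data.frame with `feature`, `score`
#'   (chi-square statistic), `p_value`, `rank`.
#' @export
rank_chi2 <- function(x, y, bins = 8) {
  x <- as.data.frame(x)
  y <- as.factor(y)
  stat <- p <- numeric(ncol(x))
  for (i in seq_len(ncol(x))) {
    b <- equal_freq_bins(x[[i]], bins)
    if (length(unique(b)) < 2) { stat[i] <- 0; p[i] <- 1; next }
    tab <- table(b, y)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat[i] <- sum((tab - E)^2 / E)
    p[i] <- stats::pchisq(stat[i], (nrow(tab) - 1) * (ncol(tab) - 1),
                          lower.tail = FALSE)
  }
  names(stat) <- names(p) <- names(x)
  ordn <- order(-stat, names(stat))
  structure(data.frame(feature = names(stat)[ordn],
                       score = as.numeric(stat[ordn]),
                       p_value = as.numeric(p[ordn]),
                       rank = seq_along(stat)),
            class = c("feature_ranking", "data.frame"),
            method = "chi2")
}

#' Consensus of the top-ranked features across methods
#'
#' The union of each method's top `n` features, annotated with the
#' per-method ranks (NA where a feature is outside a method's top list).
#'
#' @param rankings named list of `feature_ranking` objects.
#' @param n how many top features per method (default 150).
#' @return data.frame with `feature`, one `rank_<method>` column per
#'   ranking, and `n_methods` (how many top lists contain the feature),
#'   ordered by `n_methods` then best rank.
#' @export
consensus_top_features <- function(rankings, n = 150) {
  if (!length(rankings)) stopf("need at least one ranking")
  if (is.null(names(rankings)))
    names(rankings) <- vapply(rankings, function(r) attr(r, "method") %||% "m",
                              character(1))
  tops <- lapply(rankings, function(r) utils::head(r$feature, n))
  feats <- sort(unique(unlist(tops)))
  out <- data.frame(feature = feats)
  for (m in names(rankings)) {
    rk <- match(feats, rankings[[m]]$feature)
    rk[!(feats %in% tops[[m]])] <- NA
    out[[paste0("rank_", m)]] <- rk
  }
  rkcols <- grep("^rank_", names(out))
  out$n_methods <- rowSums(!is.na(out[rkcols]))
  best <- apply(out[rkcols], 1, min, na.rm = TRUE)
  out <- out[order(-out$n_methods, best, out$feature), ]
  rownames(out) <- NULL
  out
}
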