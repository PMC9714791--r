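## Decorrelated ranked feature analysis (DRFA).
##
## Correlated behavioral features are whitened by the pooled within-group
## covariance (with analytic shrinkage when needed); the decorrelated
## components are ranked by between-group separation and the top k kept.
## Groups are modelled as Gaussian "clouds" in that space, and separation
## between two clouds is scored by the Bhattacharyya overlap rescaled so
## that identical distributions give 50% and disjoint ones 100%.

## Ledoit-Wolf-style analytic shrinkage of a pooled covariance toward a
## scaled identity.  `resid` holds within-group-centred rows.
.lw_shrinkage <- function(resid) {
  n <- nrow(resid)
  p <- ncol(resid)
  S <- crossprod(resid) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) return(list(sigma = S, lambda = 0))
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- resid[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  lambda <- b2 / d2
  list(sigma = lambda * diag(mu, p) + (1 - lambda) * S, lambda = lambda)
}

#' Fit a decorrelated ranked feature space
#'
#' Features are standardised (global centre, pooled within-group SD),
#' whitened by the pooled within-group covariance, and the resulting
#' statistically independent components are ranked by a between-group
#' separation score: the subject-weighted variance of the group means
#' along each component (for two groups this is the squared standardised
#' mean difference up to a constant).  The top `k` components are kept.
#'
#' @param x numeric matrix, subjects x features.
#' @param groups group label per subject (>= 2 groups, each with >= 3
#'   subjects).
#' @param k retained dimensions; default all.
#' @param shrinkage `NULL` for analytic (Ledoit-Wolf) shrinkage toward a
#'   scaled identity, or a fixed intensity in `[0, 1]` (0 = raw pooled
#'   covariance, which must then be nonsingular).
#' @return object of class `"drf_space"`: `center`, `scale`, `transform`
#'   (features x k), `scores` (ranking criterion per retained component),
#'   `k`, `shrinkage_lambda`, `feature_names`.
#' @export
fit_drf_space <- function(x, groups, k = NULL, shrinkage = NULL) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("every group needs >= 3 subjects")
  if (any(!is.finite(x))) stop("x must be complete and finite")
  p <- ncol(x)
  if (is.null(k)) k <- p
  if (k > p) stop("k exceeds the number of features")

  center <- colMeans(x)
  ## within-group residuals on the centred data
  xc <- sweep(x, 2L, center)
  gm <- apply(xc, 2L, function(col) ave(col, groups))
  resid <- xc - gm
  pooled_sd <- sqrt(colSums(resid^2) / (nrow(x) - nlevels(groups)))
  if (any(pooled_sd <= 0)) {
    if (is.null(shrinkage) || shrinkage > 0) {
      pooled_sd[pooled_sd <= 0] <- 1  # constant feature; shrinkage handles it
    } else stop("constant feature with shrinkage disabled")
  }
  xs <- sweep(xc, 2L, pooled_sd, "/")
  resid_s <- sweep(resid, 2L, pooled_sd, "/")

  if (is.null(shrinkage)) {
    sl <- .lw_shrinkage(resid_s)
    sigma <- sl$sigma
    lambda <- sl$lambda
  } else {
    stopifnot(shrinkage >= 0, shrinkage <= 1)
    S <- crossprod(resid_s) / nrow(resid_s)
    mu <- sum(diag(S)) / p
    sigma <- shrinkage * diag(mu, p) + (1 - shrinkage) * S
    lambda <- shrinkage
  }
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values))
    stop("singular pooled covariance; enable shrinkage")
  W <- ev$vectors %*% diag(1 / sqrt(ev$values), p)

  y <- xs %*% W
  ## between-group separation per component: weighted variance of means
  ng <- as.vector(table(groups))
  means <- rowsum(y, groups) / ng
  grand <- colMeans(y)
  scores <- colSums(ng * sweep(means, 2L, grand)^2) / nrow(y)
  ord <- order(scores, decreasing = TRUE)[seq_len(k)]

  structure(list(center = center, scale = pooled_sd,
                 transform = W[, ord, drop = FALSE],
                 scores = scores[ord], k = k,
                 shrinkage_lambda = lambda,
                 feature_names = colnames(x)),
            class = "drf_space")
}

#' @export
print.drf_space <- function(x, ...) {
  cat(sprintf("<drf_space> %d features -> %d decorrelated components (shrinkage %.3g)\n",
              length(x$center), x$k, x$shrinkage_lambda))
  invisible(x)
}

#' Map data through a fitted DRF space
#'
#' @param space a [fit_drf_space()] result.
#' @param x subjects x features matrix with the same features.
#' @return subjects x k matrix of decorrelated coordinates.
#' @export
drf_transform <- function(space, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(space$center))
    stop("feature count does not match the fitted space")
  if (!is.null(space$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), space$feature_names))
    stop("feature names do not match the fitted space")
  sweep(sweep(x, 2L, space$center), 2L, space$scale, "/") %*% space$transform
}

#' Fit a Gaussian cloud to one group
#'
#' @param y subjects x k coordinates (already decorrelated).
#' @param label group label.
#' @param reg ridge added to the covariance diagonal when it is not
#'   positive definite (scaled by the mean variance).
#' @return object of class `"drfa_cloud"` with `mean`, `cov`, `n`.
#' @export
fit_cloud <- function(y, label = "group", reg = 1e-8) {
  y <- as.matrix(y)
  if (nrow(y) < 3L) stop("need >= 3 subjects to fit a cloud")
  m <- colMeans(y)
  S <- stats::cov(y)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= reg * max(abs(ev))) {
    S <- S + diag(max(mean(diag(S)), 1) * sqrt(reg), ncol(y))
  }
  structure(list(label = label, mean = m, cov = S, n = nrow(y)),
            class = "drfa_cloud")
}

.logdet <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)

#' Discrimination Index between two Gaussian clouds
#'
#' Overlap is the Bhattacharyya coefficient
#' \eqn{BC = \exp(-D_B)} with
#' \eqn{D_B = \frac18 d^\top \bar\Sigma^{-1} d +
#'   \frac12 \log\frac{\det\bar\Sigma}{\sqrt{\det\Sigma_1\det\Sigma_2}}},
#' \eqn{d} the mean difference and \eqn{\bar\Sigma} the average
#' covariance.  The index is `50 + 50 * (1 - BC)`: 50% means no
#' separation, 100% complete segregation.  Symmetric in its arguments.
#'
#' @param a,b `drfa_cloud` objects of the same dimension.
#' @return index in `[50, 100]` (percent).
#' @export
#' @examples
#' y <- matrix(rnorm(60), 20)
#' cl <- fit_cloud(y)
#' discrimination_index(cl, cl)  # exactly 50
discrimination_index <- function(a, b) {
  stopifnot(inherits(a, "drfa_cloud"), inherits(b, "drfa_cloud"))
  if (length(a$mean) != length(b$mean)) stop("cloud dimensions differ")
  Sbar <- (a$cov + b$cov) / 2
  d <- a$mean - b$mean
  db <- 0.125 * sum(d * solve(Sbar, d)) +
    0.5 * (.logdet(Sbar) - 0.5 * (.logdet(a$cov) + .logdet(b$cov)))
  bc <- exp(-max(db, 0))       # db >= 0 analytically; guard rounding
  bc <- min(max(bc, 0), 1)
  50 + 50 * (1 - bc)
}

## One full DRFA pass on a two-group matrix: space fit, clouds, index.
.di_pipeline <- function(x, groups, k, shrinkage) {
  space <- fit_drf_space(x, groups, k = k, shrinkage = shrinkage)
  y <- drf_transform(space, x)
  lv <- levels(as.factor(groups))
  a <- fit_cloud(y[groups == lv[1L], , drop = FALSE], lv[1L])
  b <- fit_cloud(y[groups == lv[2L], , drop = FALSE], lv[2L])
  discrimination_index(a, b)
}

#' Permutation p-value for a two-group Discrimination Index
#'
#' The whole pipeline (space fit, cloud fit, index) is recomputed for each
#' relabelling; the add-one estimator
#' `p = (1 + #permuted >= observed) / (n_perm + 1)` avoids p = 0.
#'
#' @param x subjects x features matrix.
#' @param groups two-level label vector.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param k,shrinkage passed to [fit_drf_space()]; `k` defaults to
#'   `min(n_features, n_subjects - 4)` to keep cloud covariances stable.
#' @return list of class `"discrimination"`: `index` (observed),
#'   `pvalue`, `n_permutations`.
#' @export
permutation_pvalue <- function(x, groups, n_perm = 1000, seed = NULL,
                               k = NULL, shrinkage = NULL) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.null(k)) k <- max(1L, min(ncol(x), nrow(x) - 4L))
  observed <- .di_pipeline(x, groups, k, shrinkage)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    gp <- sample(groups)
    if (.di_pipeline(x, gp, k, shrinkage) >= observed) exceed <- exceed + 1L
  }
  structure(list(index = observed,
                 pvalue = (1 + exceed) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "discrimination")
}

#' @export
print.discrimination <- function(x, ...) {
  cat(sprintf("Discrimination Index %.1f%% (p = %.4g, %d permutations)\n",
              x$index, x$pvalue, x$n_permutations))
  invisible(x)
}

#' Project a treated group into a fitted reference space
#'
#' The reference space is typically fitted on the disease and control
#' groups across ages (a 6-group disease/age space); the lowered group's
#' subjects are mapped through the fixed transform and compared with each
#' reference cloud.
#'
#' @param space fitted [fit_drf_space()] on the reference groups.
#' @param ref_clouds named list of `drfa_cloud` objects in that space.
#' @param x subjects x features matrix of the treated group.
#' @param label label for the projected cloud.
#' @return list: `cloud` (the projected group), `distances` (Euclidean
#'   distance from the projected mean to each reference cloud mean) and
#'   `indices` (Discrimination Index versus each reference cloud).
#' @export
project_group <- function(space, ref_clouds, x, label = "lowered") {
  stopifnot(inherits(space, "drf_space"), length(ref_clouds) >= 1L)
  y <- drf_transform(space, x)
  cl <- fit_cloud(y, label)
  dist <- vapply(ref_clouds, function(r) sqrt(sum((cl$mean - r$mean)^2)),
                 numeric(1))
  idx <- vapply(ref_clouds, function(r) discrimination_index(cl, r),
                numeric(1))
  list(cloud = cl, distances = dist, indices = idx)
}

#' Per-subject rescue scores on the disease-to-control axis
#'
#' Each treated subject is projected orthogonally onto the axis joining
#' the disease and control cloud means and rescaled affinely so the
#' disease mean maps to 0 and the control mean to 100.  Scores outside
#' `[0, 100]` are reported unclipped.
#'
#' @param space fitted reference [fit_drf_space()].
#' @param disease_cloud,control_cloud `drfa_cloud` anchors in that space.
#' @param x subjects x features matrix of the treated group.
#' @return numeric vector of scores, one per subject.
#' @export
rescue_score <- function(space, disease_cloud, control_cloud, x) {
  u <- control_cloud$mean - disease_cloud$mean
  nu2 <- sum(u^2)
  if (nu2 < .Machine$double.eps) stop("cloud means coincide")
  y <- drf_transform(space, x)
  proj <- sweep(y, 2L, disease_cloud$mean) %*% u / nu2
  100 * as.numeric(proj)
}
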