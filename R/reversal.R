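## Posterior-probability reversal classification.
##
## The treatment effect of a gene is modelled as a multiple of its disease
## effect on the log2 scale, Delta_treat = alpha * Delta_disease.  Both
## effects are observed with normal uncertainty (estimate, SE) and treated
## as independent.  The posterior probability that alpha falls in each of
## five classes is obtained by quasi-Monte-Carlo integration over a grid of
## quantiles of the two marginal normals.

#' Reversal class labels and boundaries
#'
#' Five classes of the reversal multiplier \eqn{\alpha}: super-reversal
#' (\eqn{\alpha \le -1.3}), full reversal \eqn{(-1.3, -0.7]}, partial
#' reversal \eqn{(-0.7, -0.3]}, negligible reversal \eqn{(-0.3, 0.3]} and
#' exacerbation (\eqn{\alpha > 0.3}).  Boundary values are assigned to the
#' stronger-reversal side; these are measure-zero events, but the rule is
#' fixed and documented.
#'
#' @return `reversal_classes()` returns the five labels in order from
#'   strongest reversal to exacerbation; `alpha_boundaries()` the four
#'   ordered cut points.
#' @export
#' @examples
#' reversal_classes()
reversal_classes <- function() {
  c("super", "full", "partial", "negligible", "exacerbation")
}

#' @rdname reversal_classes
#' @export
alpha_boundaries <- function() c(-1.3, -0.7, -0.3, 0.3)

#' Classify a reversal multiplier
#'
#' @param alpha numeric vector of reversal multipliers; must be finite
#'   (`NaN`/`NA` are rejected).
#' @return factor with levels [reversal_classes()].
#' @export
#' @examples
#' classify_alpha(c(-1.5, -1, -0.5, 0, 1))
classify_alpha <- function(alpha) {
  if (any(is.na(alpha))) stop("alpha must not contain NA/NaN")
  cut(alpha,
      breaks = c(-Inf, alpha_boundaries(), Inf),
      labels = reversal_classes(),
      right = TRUE)
}

#' Per-gene reversal-class probabilities on a quantile grid
#'
#' Places `n_grid` points at equally spaced quantile levels
#' \eqn{(k - 0.5)/n} of each marginal normal (disease on one axis,
#' treatment on the other), computes \eqn{\alpha = treat/disease} at each of
#' the \eqn{n^2} grid nodes, classifies it, and returns the
#' weight-normalised class frequencies.  Under quantile placement every
#' node carries equal weight \eqn{1/n^2}: the placement itself encodes the
#' bivariate normal density, so the density acts as an implicit importance
#' weight.  An explicit equal-spacing-in-x grid with density weights is
#' available via `weighting = "density"` for sensitivity checks.
#'
#' Grid nodes where the disease value is exactly 0 are classified as
#' exacerbation when the treatment value is nonzero (the ratio diverges and
#' the rule is conservative against claiming rescue) and negligible when
#' both are zero.
#'
#' @param delta_disease,se_disease disease-contrast log2 fold change and
#'   its standard error (SE > 0).
#' @param delta_treat,se_treat treatment-contrast log2 fold change
#'   (lowered group vs disease group, so \eqn{\alpha = -1} is exact return
#'   to control) and its standard error.
#' @param n_grid points per axis; default 121.
#' @param weighting `"quantile"` (default, equal weights at quantile
#'   nodes) or `"density"` (equally spaced nodes over ±5 SD, bivariate
#'   normal density weights).
#' @return named numeric vector of five probabilities summing to 1.
#' @export
#' @examples
#' reversal_probs(1, 0.01, -1, 0.01)          # point mass near alpha = -1
reversal_probs <- function(delta_disease, se_disease,
                           delta_treat, se_treat,
                           n_grid = 121,
                           weighting = c("quantile", "density")) {
  weighting <- match.arg(weighting)
  if (!is.finite(delta_disease) || !is.finite(delta_treat))
    stop("effect estimates must be finite")
  if (!is.finite(se_disease) || se_disease <= 0 ||
      !is.finite(se_treat)   || se_treat  <= 0)
    stop("standard errors must be positive")
  if (n_grid < 3) stop("n_grid must be at least 3")

  if (weighting == "quantile") {
    p <- (seq_len(n_grid) - 0.5) / n_grid
    d <- stats::qnorm(p, delta_disease, se_disease)
    t <- stats::qnorm(p, delta_treat, se_treat)
    w_d <- rep(1 / n_grid, n_grid)
    w_t <- w_d
  } else {
    d <- seq(delta_disease - 5 * se_disease, delta_disease + 5 * se_disease,
             length.out = n_grid)
    t <- seq(delta_treat - 5 * se_treat, delta_treat + 5 * se_treat,
             length.out = n_grid)
    w_d <- stats::dnorm(d, delta_disease, se_disease)
    w_t <- stats::dnorm(t, delta_treat, se_treat)
    w_d <- w_d / sum(w_d)
    w_t <- w_t / sum(w_t)
  }

  ## alpha[i, j] = t[i] / d[j]; weight[i, j] = w_t[i] * w_d[j]
  alpha <- outer(t, d, "/")
  w <- outer(w_t, w_d)

  cls <- matrix(as.integer(classify_alpha(ifelse(is.finite(alpha), alpha, 0))),
                nrow = n_grid)
  ## ratio at disease == 0: exacerbation unless treat is also 0
  bad <- !is.finite(alpha)
  if (any(bad)) {
    tz <- matrix(rep(t == 0, times = n_grid), nrow = n_grid)
    cls[bad & !tz] <- 5L  # exacerbation
    cls[bad & tz]  <- 4L  # negligible (0/0 node)
  }

  probs <- vapply(1:5, function(k) sum(w[cls == k]), numeric(1))
  probs <- probs / sum(probs)
  names(probs) <- reversal_classes()
  probs
}

#' Assign a reversal category from class probabilities
#'
#' If the negligible-class probability is at least `neg_cut` the gene is
#' called negligibly reversed regardless of the other classes; otherwise
#' the class with the highest probability among the remaining four wins,
#' ties broken toward the stronger-reversal class (super > full > partial >
#' exacerbation).
#'
#' @param probs named (or ordered as [reversal_classes()]) vector of five
#'   probabilities summing to 1 (tolerance `1e-6`).
#' @param neg_cut override threshold on P(negligible); default 0.05.
#' @return a single class label (character).
#' @export
assign_category <- function(probs, neg_cut = 0.05) {
  if (length(probs) != 5L) stop("probs must have five elements")
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  cls <- reversal_classes()
  if (!is.null(names(probs))) probs <- probs[cls]
  if (probs[4L] >= neg_cut) return("negligible")
  ## candidate order encodes the tie-break: stronger reversal first
  cand <- c(1L, 2L, 3L, 5L)
  cls[cand[which.max(probs[cand])]]
}

#' Reversal analysis of aligned disease and treatment tables
#'
#' Joins two per-gene effect tables on `gene_id`, runs [reversal_probs()]
#' and [assign_category()] per gene, and reports the Overall Reversal
#' Probability ORP = 1 − P(negligible).
#'
#' @param disease,treatment data frames with columns `gene_id`, `log2fc`,
#'   `lfc_se` (one row per gene).
#' @param genes optional character vector restricting the analysis (e.g. a
#'   signature's members); genes absent from either table are an error.
#' @param n_grid,weighting,neg_cut passed through.
#' @return data frame: `gene_id`, `p_super`, `p_full`, `p_partial`,
#'   `p_negligible`, `p_exacerbation`, `category`, `orp`.
#' @export
reversal_table <- function(disease, treatment, genes = NULL,
                           n_grid = 121, weighting = "quantile",
                           neg_cut = 0.05) {
  for (tb in list(disease, treatment))
    stopifnot(all(c("gene_id", "log2fc", "lfc_se") %in% names(tb)))
  if (is.null(genes)) genes <- intersect(disease$gene_id, treatment$gene_id)
  miss <- setdiff(genes, intersect(disease$gene_id, treatment$gene_id))
  if (length(miss))
    stop("genes missing from input tables: ", paste(miss, collapse = ", "))
  di <- disease[match(genes, disease$gene_id), ]
  tr <- treatment[match(genes, treatment$gene_id), ]
  pm <- t(mapply(function(dd, sd, dt, st)
    reversal_probs(dd, sd, dt, st, n_grid = n_grid, weighting = weighting),
    di$log2fc, di$lfc_se, tr$log2fc, tr$lfc_se))
  category <- apply(pm, 1L, assign_category, neg_cut = neg_cut)
  out <- data.frame(gene_id = genes,
                    p_super = pm[, 1L], p_full = pm[, 2L],
                    p_partial = pm[, 3L], p_negligible = pm[, 4L],
                    p_exacerbation = pm[, 5L],
                    category = category,
                    orp = 1 - pm[, 4L],
                    row.names = NULL)
  out
}

#' Summarise reversal results for one lowering scenario
#'
#' @param results data frame from [reversal_table()] (needs `category` and
#'   `orp` columns).
#' @param orp_cut significance bar on the ORP; a gene counts as
#'   significantly reversed when `orp > orp_cut` strictly. Default 0.95.
#' @return list with per-category counts and percentages, the number and
#'   percentage of genes above the ORP bar, and the count of reversed
#'   genes (super + full + partial).
#' @export
summarize_reversal <- function(results, orp_cut = 0.95) {
  stopifnot(nrow(results) > 0L,
            all(c("category", "orp") %in% names(results)))
  n <- nrow(results)
  cls <- reversal_classes()
  counts <- vapply(cls, function(k) sum(results$category == k), integer(1))
  n_sig <- sum(results$orp > orp_cut)
  list(n_genes = n,
       counts = counts,
       percent = 100 * counts / n,
       n_orp_significant = n_sig,
       percent_orp_significant = 100 * n_sig / n,
       n_reversed = sum(counts[c("super", "full", "partial")]),
       orp_cut = orp_cut)
}
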