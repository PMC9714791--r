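## Hypergeometric gene-set overrepresentation and per-set reversal
## summaries (the data behind a radar plot of reversal percentages).

#' Construct a gene-set collection over a universe
#'
#' Sets are restricted to the universe; sets that become empty after
#' restriction are dropped with a warning.
#'
#' @param sets named list of character vectors of gene ids.
#' @param universe character vector; typically all genes observed in the
#'   differential-expression table (the standard enrichment default, and
#'   the only universe the pipeline observes).
#' @return object of class `"geneset_collection"`.
#' @export
geneset_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) empty after universe restriction")
    restricted <- restricted[!empty]
  }
  structure(list(sets = restricted, universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric overrepresentation of a signature in gene sets
#'
#' For each set of size K in a universe of size N, with a signature of
#' size n (after restriction to the universe) overlapping the set in k
#' genes, the upper-tail hypergeometric probability
#' P(overlap >= k) is computed; q-values are BH adjustments over all
#' tested sets.  Results are sorted by gene ratio (k/n) descending, the
#' usual ordering for top-k reporting.
#'
#' @param signature a `signature_set` or character vector of gene ids.
#' @param collection a [geneset_collection()].
#' @return data frame: `set`, `k` (overlap), `K` (set size), `n`
#'   (signature size), `N` (universe size), `gene_ratio`, `pvalue`,
#'   `qvalue`.
#' @export
hypergeom_enrich <- function(signature, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  genes <- intersect(genes, collection$universe)
  if (length(genes) == 0L)
    stop("signature is empty after restriction to the universe")
  N <- length(collection$universe)
  n <- length(genes)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(genes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               gene_ratio = k / n, pvalue = p)
  })
  out <- do.call(rbind, res)
  out$qvalue <- bh_adjust(out$pvalue)
  out[order(-out$gene_ratio, out$pvalue), , drop = FALSE]
}

#' Per-set reversal percentages across lowering scenarios
#'
#' For each gene set and each scenario, the percentage of signature genes
#' belonging to the set whose Overall Reversal Probability exceeds
#' `orp_cut`.  This is the table a reversal radar plot is drawn from.
#'
#' @param results_by_scenario named list of data frames from
#'   [reversal_table()] (columns `gene_id` and `orp`), one per scenario.
#' @param collection a [geneset_collection()].
#' @param signature `signature_set` or character vector; every signature
#'   gene must have a reversal result in every scenario.
#' @param orp_cut ORP threshold; default 0.95 (strict).
#' @return data frame with one row per retained gene set: `set`,
#'   `n_signature_genes`, and one percentage column per scenario. Sets
#'   disjoint from the signature are dropped with a warning.
#' @export
reversal_fraction_by_set <- function(results_by_scenario, collection,
                                     signature, orp_cut = 0.95) {
  stopifnot(inherits(collection, "geneset_collection"),
            length(results_by_scenario) >= 1L,
            !is.null(names(results_by_scenario)))
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  for (nm in names(results_by_scenario)) {
    miss <- setdiff(genes, results_by_scenario[[nm]]$gene_id)
    if (length(miss))
      stop("scenario '", nm, "' lacks reversal results for: ",
           paste(utils::head(miss, 10L), collapse = ", "),
           if (length(miss) > 10L) sprintf(" (+%d more)", length(miss) - 10L))
  }
  members <- lapply(collection$sets, intersect, genes)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) disjoint from the signature")
    members <- members[!empty]
  }
  pct <- sapply(names(results_by_scenario), function(nm) {
    res <- results_by_scenario[[nm]]
    orp <- res$orp[match(genes, res$gene_id)]
    names(orp) <- genes
    vapply(members, function(m) 100 * mean(orp[m] > orp_cut), numeric(1))
  })
  pct <- matrix(pct, nrow = length(members),
                dimnames = list(names(members), names(results_by_scenario)))
  out <- data.frame(set = names(members),
                    n_signature_genes = lengths(members),
                    pct, row.names = NULL, check.names = FALSE)
  out
}
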