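## Differential-expression signatures: BH adjustment, fold-change filters,
## responder exclusion, and set algebra across ages/tissues.

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up construction: sort p ascending, multiply by n/rank,
#' take the cumulative minimum from the largest rank down, clip to `[0, 1]`,
#' and return values in the original input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`; must be nonempty.
#' @return adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvalues)
  o <- order(pvalues)
  adj <- pvalues[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Construct a signature object
#'
#' A signature is a named set of gene identifiers with optional per-gene
#' directions (sign of log2 fold change) and free-text provenance.
#'
#' @param genes character vector of gene ids (duplicates rejected).
#' @param name label for the signature.
#' @param directions optional named vector (+1/-1) covering exactly `genes`.
#' @param provenance free-text description (tissue, age, thresholds).
#' @return an object of class `"signature_set"`.
#' @export
signature_set <- function(genes, name = "signature", directions = NULL,
                          provenance = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids in signature")
  if (!is.null(directions)) {
    if (!setequal(names(directions), genes))
      stop("directions must cover exactly the member genes")
    directions <- directions[genes]
  }
  structure(list(name = name, genes = genes, directions = directions,
                 provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d genes\n", x$name, length(x$genes)))
  if (length(x$provenance)) cat("  ", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$genes)

#' Build a disease signature from a per-gene effect table
#'
#' A gene enters the signature iff its adjusted p-value is below `padj_cut`
#' and its fold change is at least `min_fc` in either direction, i.e.
#' `|log2fc| >= log2(1 + min_fc)`.  When the table carries no `padj`
#' column, BH adjustment of `pvalue` is performed internally (and recorded
#' in the provenance); a provided `padj` column is used as-is.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `pvalue`
#'   and optionally `padj`.
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @param min_fc minimum fractional fold change (default 0.20, i.e. 20%
#'   in either direction).
#' @param name,provenance passed to [signature_set()].
#' @return a `signature_set` with directions from the sign of `log2fc`.
#' @export
build_signature <- function(table, padj_cut = 0.05, min_fc = 0.20,
                            name = "signature", provenance = character()) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(table)), min_fc > 0)
  if (anyDuplicated(table$gene_id)) stop("duplicate gene_id in table")
  if (!"padj" %in% names(table)) {
    if (!"pvalue" %in% names(table))
      stop("table must carry padj or pvalue")
    table$padj <- bh_adjust(table$pvalue)
    padj_src <- "padj computed internally by BH"
  } else {
    padj_src <- "padj column used as provided"
  }
  lfc_cut <- log2(1 + min_fc)
  keep <- table$padj < padj_cut & abs(table$log2fc) >= lfc_cut
  genes <- table$gene_id[keep]
  dirs <- sign(table$log2fc[keep])
  names(dirs) <- genes
  signature_set(genes, name = name, directions = dirs,
                provenance = c(provenance,
                               sprintf("padj < %g; |log2fc| >= log2(1 + %g)",
                                       padj_cut, min_fc),
                               padj_src))
}

#' Remove responder genes from a signature
#'
#' Genes that respond to the vehicle/inducer alone (e.g. IPTG in wild-type
#' animals) are confounders and are excluded from the disease signature.
#'
#' @param sig,responders `signature_set` objects.
#' @return `sig` minus the responder genes, provenance annotated.
#' @export
exclude_responders <- function(sig, responders) {
  keep <- setdiff(sig$genes, responders$genes)
  dirs <- if (is.null(sig$directions)) NULL else sig$directions[keep]
  signature_set(keep, name = sig$name, directions = dirs,
                provenance = c(sig$provenance,
                               sprintf("excluded %d responder genes (%s)",
                                       length(sig$genes) - length(keep),
                                       responders$name)))
}

#' Combine two signatures across ages or tissues
#'
#' @param a,b `signature_set` objects.
#' @return list with `union` and `intersection` signatures and a `sizes`
#'   report (`|a|`, `|b|`, `|a intersect b|`, `|a union b|`).
#' @export
#' @examples
#' a <- signature_set(paste0("g", 1:5), "six_months")
#' b <- signature_set(paste0("g", 4:8), "twelve_months")
#' combine_signatures(a, b)$sizes
combine_signatures <- function(a, b) {
  u <- union(a$genes, b$genes)
  i <- intersect(a$genes, b$genes)
  mk <- function(g, nm) signature_set(
    g, name = nm,
    provenance = sprintf("%s of %s (%d) and %s (%d)",
                         nm, a$name, length(a$genes), b$name, length(b$genes)))
  list(union = mk(u, paste0(a$name, "_union_", b$name)),
       intersection = mk(i, paste0(a$name, "_intersect_", b$name)),
       sizes = c(a = length(a$genes), b = length(b$genes),
                 intersection = length(i), union = length(u)))
}

## ---- TSV / gene-list / GMT serialisation ---------------------------------

#' Read and write per-gene effect tables
#'
#' Plain TSV with columns `gene_id`, `log2fc`, `lfc_se`, `pvalue` and
#' optionally `padj`.
#'
#' @param path file path.
#' @param table data frame to write.
#' @export
read_gene_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc")
  if (!all(need %in% names(tb)))
    stop("gene table must carry columns: ", paste(need, collapse = ", "))
  tb
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise signatures as plain gene lists
#'
#' @param sig a `signature_set`.
#' @param path file path; one gene id per line.
#' @export
write_gene_list <- function(sig, path) {
  writeLines(sig$genes, path)
  invisible(path)
}

#' Read/write gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
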