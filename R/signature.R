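# Perturbation signatures: Z-scores to two-tailed p-values and BH FDRs.
# The endpoint FDR is the penalty score used by the path-weighting engine.

#' Convert a perturbation Z-score to a two-tailed p-value
#'
#' Computes `2 * (1 - pnorm(|z|))`, the two-tailed standard-normal tail
#' probability, clamped to `[0, 1]`. Even in `z` and strictly decreasing in
#' `|z|`.
#'
#' @param z Numeric vector of finite Z-scores.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
z_to_pvalue <- function(z) {
  if (length(z) == 0) return(numeric(0))
  if (!is.numeric(z) || any(!is.finite(z))) {
    stop("z scores must be finite numbers")
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment of a p-value vector: sort ascending, scale by
#' n/rank, enforce monotonicity from the largest rank down, cap at 1, and
#' return in the original input order. This wraps `stats::p.adjust(method =
#' "BH")`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return FDR values aligned with `pvals`; elementwise at least `pvals`.
#' @export
adjust_fdr_bh <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (!is.numeric(pvals) || any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Read a perturbation signature table
#'
#' @param path Two-column TSV `gene`, `z` (header required), as produced from
#'   CMap-style level-5 moderated Z-scores.
#' @return Data frame with columns `gene` and `z`.
#' @export
read_signature_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("gene", "z"), names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed signature table '", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data.frame(gene = as.character(tab$gene), z = as.numeric(tab$z),
             stringsAsFactors = FALSE)
}

#' Score a signature: p-values and FDRs from Z-scores
#'
#' Adds two-tailed p-values and BH FDR columns to a `gene`/`z` signature
#' table. The FDR column is the endpoint penalty score: the probability-like
#' weight that the gene's expression did not actually change. FDRs must be
#' computed on the full signature before any mapping onto a network, so call
#' this before [map_signature()].
#'
#' @param signature Data frame with columns `gene` and `z`.
#' @return The signature with added columns `p` and `fdr`.
#' @export
compute_signature <- function(signature) {
  stopifnot(is.data.frame(signature), all(c("gene", "z") %in% names(signature)))
  if (anyDuplicated(signature$gene)) {
    stop("duplicate gene identifiers in signature")
  }
  signature$p <- z_to_pvalue(signature$z)
  signature$fdr <- adjust_fdr_bh(signature$p)
  signature
}

#' Map signature genes onto network nodes
#'
#' Keeps only signature entries whose gene is a node of the network; mapped
#' and unmapped counts are reported via [message()]. FDR values are carried
#' over unchanged — mapping never re-adjusts them.
#'
#' @param network A `moa_network`.
#' @param entries A scored signature ([compute_signature()]).
#' @return The subset of `entries` present in the network.
#' @export
map_signature <- function(network, entries) {
  stopifnot(inherits(network, "moa_network"), is.data.frame(entries))
  hit <- entries$gene %in% network$nodes$node
  message(sprintf("signature mapping: %d mapped / %d unmapped",
                  sum(hit), sum(!hit)))
  out <- entries[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
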