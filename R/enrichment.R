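# Pathway enrichment of loop-involved genes against the disease background.

#' Hypergeometric pathway enrichment of a gene set
#'
#' Tests whether pathway members are over-represented in a foreground gene
#' set (e.g. disease genes targeted by miRNAs inside feedback loops) relative
#' to a background (e.g. all disease genes). The p-value is the exact
#' one-sided hypergeometric upper tail: the probability of observing at
#' least `k` pathway members among `n` foreground genes drawn from a
#' background of `N` genes of which `K` are pathway members.
#'
#' @param foreground character vector of foreground gene ids; must be a
#'   subset of `background`.
#' @param background character vector of background gene ids.
#' @param pathway_members character vector of pathway gene ids (only the
#'   intersection with the background is counted).
#' @param pathway_id label for the result row.
#' @return One-row data.frame with columns `pathway_id`, `k`, `n`, `K`, `N`,
#'   `foreground_fraction`, `background_fraction`, `p_value`.
#' @examples
#' # cell-cycle-style configuration: 31 of 46 loop genes vs 125 of 379
#' pathway_enrichment(paste0("fg", 1:46), paste0("fg", 1:379),
#'                    c(paste0("fg", 1:31), paste0("fg", 100:193)))
#' @export
pathway_enrichment <- function(foreground, background, pathway_members,
                               pathway_id = "pathway") {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    stop("foreground gene not in background: ", extra[1])
  }
  members <- intersect(unique(as.character(pathway_members)), background)
  k <- length(intersect(foreground, members))
  n <- length(foreground)
  K <- length(members)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(
    pathway_id = pathway_id, k = k, n = n, K = K, N = N,
    foreground_fraction = if (n > 0) k / n else NA_real_,
    background_fraction = if (N > 0) K / N else NA_real_,
    p_value = p,
    stringsAsFactors = FALSE)
}

#' Enrichment over multiple pathways
#'
#' Applies [pathway_enrichment()] to every pathway in an annotation table,
#' optionally adjusting p-values with Benjamini-Hochberg.
#'
#' @inheritParams pathway_enrichment
#' @param pathway_table data.frame with columns `pathway_id`, `gene_id`.
#' @param adjust `"none"` (default; single-pathway comparisons need no
#'   correction) or `"BH"`.
#' @return data.frame with one row per pathway and, when `adjust = "BH"`, an
#'   extra `p_adjusted` column.
#' @export
enrich_pathways <- function(foreground, background, pathway_table,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ids <- sort(unique(pathway_table$pathway_id))
  out <- do.call(rbind, lapply(ids, function(pid) {
    pathway_enrichment(
      foreground, background,
      pathway_table$gene_id[pathway_table$pathway_id == pid], pid)
  }))
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
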