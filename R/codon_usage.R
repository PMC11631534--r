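# Codon-usage accounting over the CDS database and ranking of genes by
# their content of codons a variant tRNA could mistranslate.

#' Codon usage table
#'
#' Counts every coding codon in the database (stop codons are trimmed at
#' load) and the corresponding fractions.
#'
#' @param db A `coding_db`.
#' @return data.frame with columns `codon`, `count`, `fraction`, ordered
#'   by codon. Fractions sum to 1.
#' @export
codon_usage_table <- function(db) {
  if (length(db) == 0L) stop("empty database", call. = FALSE)
  counts <- integer(0)
  all_codons <- unlist(lapply(db, function(g) {
    n <- nchar(g$cds)
    substring(g$cds, seq(1L, n, 3L), seq(3L, n, 3L))
  }), use.names = FALSE)
  tab <- table(all_codons)
  out <- data.frame(codon = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$count / sum(out$count)
  out <- out[order(out$codon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by content of target codons
#'
#' Genes are ordered by their count of codons in `codon_set` (descending);
#' with `normalize = TRUE` the ranking criterion is the count divided by
#' the gene's total codon count (density). Ties break lexicographically
#' by `gene_id` so the ordering is deterministic.
#'
#' @param db A `coding_db`.
#' @param codon_set Character vector of DNA codons (e.g. the four ACN
#'   threonine codons).
#' @param normalize Rank by density instead of raw count.
#' @return data.frame `gene_id`, `n_target_codons`, `n_codons`,
#'   `density`, in rank order.
#' @export
rank_genes_by_target_codons <- function(db, codon_set, normalize = FALSE) {
  if (length(codon_set) == 0L) stop("codon_set is empty", call. = FALSE)
  codon_set <- toupper(codon_set)
  bad <- codon_set[nchar(codon_set) != 3L | grepl("[^ACGT]", codon_set)]
  if (length(bad))
    stop("invalid codon(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(db, function(g) {
    n <- nchar(g$cds)
    cods <- substring(g$cds, seq(1L, n, 3L), seq(3L, n, 3L))
    data.frame(gene_id = g$gene_id,
               n_target_codons = sum(cods %in% codon_set),
               n_codons = length(cods), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$density <- out$n_target_codons / out$n_codons
  key <- if (normalize) out$density else out$n_target_codons
  out <- out[order(-key, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a ranked gene list
#'
#' Writes the ranking as TSV (for, e.g., external GO-enrichment tools).
#'
#' @param ranking Output of [rank_genes_by_target_codons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
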