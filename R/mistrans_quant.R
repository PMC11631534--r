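# Residue- and codon-level misincorporation frequencies: the
# sibling-peptide rule, the unique-localization rule, per-codon counting
# and anticodon-codon decoding classification.

#' Sibling-peptide filter
#'
#' Retains a substituted unique peptide only when its non-substituted
#' (wild-type) sibling — the unique peptide with the identical base
#' sequence and no substitution — was also observed in the same
#' replicate. This is the evidence rule for counting a misincorporation
#' event, and it cancels detection bias because numerator and wild-type
#' denominator events then share the same detectability gate.
#'
#' @param unique_peptides A `unique_peptides` table
#'   (one replicate; see [collapse_to_unique()]).
#' @return The substituted subset with an observed wild-type sibling.
#' @export
sibling_filter <- function(unique_peptides) {
  up <- unique_peptides
  wt_seqs <- unique(up$base_sequence[!up$is_substituted])
  out <- up[up$is_substituted & up$base_sequence %in% wt_seqs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue-level misincorporation frequency
#'
#' Frequency = 100 x (unique substituted peptides passing the sibling
#' rule) / (unique peptides whose wild-type base sequence contains at
#' least one origin residue). Substituted and wild-type forms are counted
#' as distinct identity tuples; substituted forms are members of the
#' denominator through their base sequence, which contains the origin
#' residue pre-substitution (otherwise high misincorporation would shrink
#' its own denominator).
#'
#' @param unique_peptides A `unique_peptides` table for one replicate.
#' @param substitution A [substitution_spec()].
#' @param sibling_rule Apply [sibling_filter()] to the numerator
#'   (default TRUE, the published counting rule).
#' @param count `"unique"` (default) counts unique peptide identity
#'   tuples; `"psm"` weights each tuple by its spectral count.
#' @param denominator_includes_substituted Keep substituted forms in the
#'   denominator (default TRUE).
#' @param replicate_id Label carried into the result.
#' @return One-row data.frame of class `frequency_result`: `replicate_id`,
#'   `substitution`, `n_mistranslated`, `n_total`, `frequency_pct`.
#'   A zero denominator yields `frequency_pct = NA` with a warning
#'   (undefined, not 0).
#' @export
mistranslation_frequency <- function(unique_peptides, substitution,
                                     sibling_rule = TRUE,
                                     count = c("unique", "psm"),
                                     denominator_includes_substituted = TRUE,
                                     replicate_id = "rep1") {
  stopifnot(inherits(substitution, "substitution_spec"))
  count <- match.arg(count)
  up <- unique_peptides
  w <- function(x) if (count == "psm") sum(x$psm_count) else nrow(x)

  subs <- up[up$is_substituted &
               up$sub_from == substitution$from_aa &
               up$sub_to == substitution$to_aa, , drop = FALSE]
  if (sibling_rule) {
    wt_seqs <- unique(up$base_sequence[!up$is_substituted])
    subs <- subs[subs$base_sequence %in% wt_seqs, , drop = FALSE]
  }

  has_origin <- grepl(substitution$from_aa, up$base_sequence, fixed = TRUE)
  denom_set <- up[has_origin &
                    (denominator_includes_substituted | !up$is_substituted),
                  , drop = FALSE]
  n_mis <- w(subs)
  n_tot <- w(denom_set)
  if (n_tot == 0L) {
    warning("no peptides contain the origin residue ",
            substitution$from_aa, "; frequency is undefined", call. = FALSE)
    freq <- NA_real_
  } else {
    freq <- 100 * n_mis / n_tot
  }
  out <- data.frame(replicate_id = replicate_id,
                    substitution = substitution$label,
                    n_mistranslated = n_mis, n_total = n_tot,
                    frequency_pct = freq, stringsAsFactors = FALSE)
  class(out) <- c("frequency_result", class(out))
  out
}

#' Unique-localization filter
#'
#' Retains a substituted peptide only when the misincorporation event can
#' be attributed to exactly one codon: (a) the peptide carries exactly
#' one substituted position, and (b) its base sequence occurs at exactly
#' one location in the protein database.
#'
#' @param substituted_peptides Substituted rows of a `unique_peptides`
#'   table (e.g. the output of [sibling_filter()]).
#' @param db A `coding_db`.
#' @param locations Optional precomputed [locate_peptides()] result for
#'   the relevant base sequences.
#' @return The retained subset with `gene_id` and `start` (0-based
#'   peptide offset in the protein) columns attached.
#' @export
unique_localization_filter <- function(substituted_peptides, db,
                                       locations = NULL) {
  sp <- substituted_peptides[lengths(substituted_peptides$sub_positions) == 1L,
                             , drop = FALSE]
  if (nrow(sp) == 0L) {
    sp$gene_id <- character(0)
    sp$start <- integer(0)
    return(sp)
  }
  if (is.null(locations))
    locations <- locate_peptides(unique(sp$base_sequence), db)
  hits <- table(locations$peptide)
  uniq <- names(hits)[hits == 1L]
  sp <- sp[sp$base_sequence %in% uniq, , drop = FALSE]
  idx <- match(sp$base_sequence, locations$peptide)
  sp$gene_id <- locations$gene_id[idx]
  sp$start <- locations$start[idx]
  rownames(sp) <- NULL
  sp
}

#' All codons coding a residue (standard genetic code)
#'
#' @param aa One-letter residue code.
#' @return Character vector of DNA codons.
#' @export
codons_for_residue <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == aa])
}

#' Per-codon misincorporation frequency
#'
#' Counting is occurrence-level: each origin-residue site in a retained
#' peptide contributes one event at its codon. For each codon coding the
#' origin residue, `n_sub_events` counts uniquely localized substituted
#' peptides (one substituted site each, sibling rule applied) whose
#' substituted residue maps to that codon, and `n_wt_events` counts
#' origin-residue occurrences at that codon within uniquely locating
#' wild-type peptides. Frequency = 100 x n_sub / (n_sub + n_wt).
#'
#' @param unique_peptides A `unique_peptides` table for one replicate.
#' @param db A `coding_db`.
#' @param substitution A [substitution_spec()].
#' @param anticodon The variant tRNA anticodon (5'->3', RNA or DNA
#'   alphabet) used to classify how each codon would be decoded.
#' @param sibling_rule Apply the sibling rule to substituted peptides.
#' @param count `"unique"` or `"psm"` event weighting, as in
#'   [mistranslation_frequency()].
#' @return data.frame of class `codon_frequency`: `codon`,
#'   `n_sub_events`, `n_wt_events`, `frequency_pct`, `decoding_class`,
#'   one row per codon of the origin residue. Attribute `"overall"`
#'   carries the event-level totals.
#' @export
per_codon_frequency <- function(unique_peptides, db, substitution,
                                anticodon, sibling_rule = TRUE,
                                count = c("unique", "psm")) {
  stopifnot(inherits(substitution, "substitution_spec"))
  count <- match.arg(count)
  origin <- substitution$from_aa
  codon_set <- codons_for_residue(origin)
  if (length(codon_set) == 0L)
    stop("no codons code for residue ", origin, call. = FALSE)
  up <- unique_peptides

  subs <- up[up$is_substituted & up$sub_from == origin &
               up$sub_to == substitution$to_aa, , drop = FALSE]
  if (sibling_rule) {
    wt_seqs <- unique(up$base_sequence[!up$is_substituted])
    subs <- subs[subs$base_sequence %in% wt_seqs, , drop = FALSE]
  }
  wt <- up[!up$is_substituted &
             grepl(origin, up$base_sequence, fixed = TRUE), , drop = FALSE]

  locations <- locate_peptides(unique(c(subs$base_sequence,
                                        wt$base_sequence)), db)
  hits <- table(locations$peptide)
  uniq <- names(hits)[hits == 1L]

  subs <- unique_localization_filter(subs, db, locations = locations)

  wt <- wt[wt$base_sequence %in% uniq, , drop = FALSE]
  idx <- match(wt$base_sequence, locations$peptide)
  wt$gene_id <- locations$gene_id[idx]
  wt$start <- locations$start[idx]

  n_sub <- stats::setNames(numeric(length(codon_set)), codon_set)
  n_wt <- n_sub
  wgt <- function(x) if (count == "psm") x$psm_count else rep(1L, nrow(x))

  if (nrow(subs)) {
    sub_codons <- vapply(seq_len(nrow(subs)), function(i) {
      codon_at(db[[subs$gene_id[i]]],
               subs$start[i] + subs$sub_positions[[i]][1])
    }, "")
    agg <- tapply(wgt(subs), sub_codons, sum)
    n_sub[names(agg)] <- n_sub[names(agg)] + agg
  }
  if (nrow(wt)) {
    wwt <- wgt(wt)
    pos_list <- gregexpr(origin, wt$base_sequence, fixed = TRUE)
    n_per <- lengths(pos_list)
    row_idx <- rep(seq_len(nrow(wt)), n_per)
    pos0 <- unlist(pos_list, use.names = FALSE) - 1L
    cds_by_gene <- vapply(db, `[[`, "", "cds")
    ri <- wt$start[row_idx] + pos0
    cods <- substring(cds_by_gene[wt$gene_id[row_idx]],
                      3L * ri + 1L, 3L * ri + 3L)
    agg <- tapply(wwt[row_idx], cods, sum)
    n_wt[names(agg)] <- n_wt[names(agg)] + agg
  }

  tot <- n_sub + n_wt
  out <- data.frame(
    codon = codon_set,
    n_sub_events = as.numeric(n_sub),
    n_wt_events = as.numeric(n_wt),
    frequency_pct = ifelse(tot > 0, 100 * n_sub / tot, 0),
    decoding_class = vapply(codon_set, function(cd)
      classify_decoding(anticodon, cd), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "overall") <- c(n_sub = sum(n_sub), n_events = sum(tot),
                            frequency_pct =
                              if (sum(tot) > 0) 100 * sum(n_sub) / sum(tot)
                              else NA_real_)
  class(out) <- c("codon_frequency", class(out))
  out
}

.WC_PAIR <- c(A = "U", U = "A", G = "C", C = "G")

.norm_rna <- function(x) chartr("T", "U", toupper(x))

#' Classify how an anticodon decodes a codon
#'
#' Anticodon bases 34-36 (given 5'->3') pair antiparallel with codon
#' positions 3-1: anticodon position 36 pairs codon position 1, 35 pairs
#' 2, and 34 pairs the codon's third (3') base, where wobble occurs.
#' Classes:
#' \describe{
#'   \item{watson_crick}{All three positions Watson-Crick paired. A34:U
#'     is classed here (the fully complementary codon) even though A34 is
#'     typically modified to inosine.}
#'   \item{wobble_I34}{A34 opposite codon-3 C or A: expected decoding if
#'     A34 is deaminated to inosine (I pairs U, C and A).}
#'   \item{wobble_GU}{G34:U or U34:G wobble.}
#'   \item{mismatch_3prime}{Positions 35/36 pair but position 34 does
#'     not, by any recognised rule.}
#'   \item{other}{A mispair at codon position 1 or 2.}
#' }
#'
#' @param anticodon,codon Three-letter strings (A/C/G/U, T accepted),
#'   both 5'->3'.
#' @return One of `"watson_crick"`, `"wobble_I34"`, `"wobble_GU"`,
#'   `"mismatch_3prime"`, `"other"`.
#' @examples
#' classify_decoding("AGU", "ACU")  # watson_crick
#' classify_decoding("AGU", "ACC")  # wobble_I34
#' classify_decoding("AGU", "ACG")  # mismatch_3prime
#' @export
classify_decoding <- function(anticodon, codon) {
  ac <- strsplit(.norm_rna(anticodon), "")[[1]]
  cd <- strsplit(.norm_rna(codon), "")[[1]]
  if (length(ac) != 3L || length(cd) != 3L ||
      !all(ac %in% names(.WC_PAIR)) || !all(cd %in% names(.WC_PAIR)))
    stop("anticodon and codon must be 3-mers over A/C/G/U (or T)",
         call. = FALSE)
  # ac[1] = position 34, ac[2] = 35, ac[3] = 36
  if (.WC_PAIR[[ac[3]]] != cd[1] || .WC_PAIR[[ac[2]]] != cd[2])
    return("other")
  a34 <- ac[1]; c3 <- cd[3]
  if (.WC_PAIR[[a34]] == c3) return("watson_crick")
  if (a34 == "A" && c3 %in% c("C", "A")) return("wobble_I34")
  if ((a34 == "G" && c3 == "U") || (a34 == "U" && c3 == "G"))
    return("wobble_GU")
  "mismatch_3prime"
}

#' Compare per-replicate frequencies between two groups
#'
#' Welch t-test on per-replicate frequency values (the study design:
#' n = 5 replicates per genotype), with optional Holm adjustment when
#' several comparisons are corrected together.
#'
#' @param groupA,groupB Numeric vectors of per-replicate frequencies
#'   (>= 2 each).
#' @param p_family Optional vector of other raw p-values corrected
#'   together with this comparison's.
#' @return data.frame with `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
compare_replicate_frequencies <- function(groupA, groupB, p_family = NULL) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 replicates per group", call. = FALSE)
  tt <- welch_t_test(groupA, groupB)
  p_adj <- holm_bonferroni(c(tt$p_value, p_family))[1]
  data.frame(statistic = tt$statistic, df = tt$df,
             p_value = tt$p_value, p_adjusted = p_adj)
}

#' Write the replicate frequency report
#'
#' TSV with one residue-level row per replicate followed by per-codon
#' rows carrying decoding classes.
#'
#' @param frequency A `frequency_result` (rows may be rbind-ed across
#'   replicates).
#' @param codon_frequency A `codon_frequency` table (or NULL).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_report <- function(frequency, codon_frequency, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(frequency, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(codon_frequency)) {
    writeLines("", con)
    utils::write.table(codon_frequency, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
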