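# Paired protein/CDS database, Lys-C in-silico digestion, peptide
# localization and codon lookup. Coordinates are 0-based half-open
# internally; file dialects are 1-based.

#' Construct a coding gene record
#'
#' A protein sequence paired with its coding DNA sequence. The CDS must
#' translate (standard genetic code) exactly to the protein; a single
#' trailing stop codon is accepted and flagged. Ambiguous nucleotides are
#' rejected because per-codon counting requires exact codon identity.
#'
#' @param gene_id Identifier.
#' @param protein Amino-acid sequence (canonical one-letter codes).
#' @param cds Coding sequence (A/C/G/T only).
#' @return A list of class `coding_gene` with fields `gene_id`, `protein`,
#'   `cds` (stop trimmed), `has_stop`.
#' @export
coding_gene <- function(gene_id, protein, cds) {
  protein <- toupper(protein)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds))
    stop("gene ", gene_id, ": CDS contains non-ACGT characters", call. = FALSE)
  if (nchar(cds) %% 3L != 0L)
    stop("gene ", gene_id, ": CDS length not a multiple of 3", call. = FALSE)
  n_aa <- nchar(protein)
  n_codon <- nchar(cds) %/% 3L
  has_stop <- FALSE
  if (n_codon == n_aa + 1L) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA"))
      stop("gene ", gene_id, ": trailing codon ", last, " is not a stop codon",
           call. = FALSE)
    has_stop <- TRUE
    cds <- substr(cds, 1L, nchar(cds) - 3L)
  } else if (n_codon != n_aa) {
    stop("gene ", gene_id, ": CDS codes for ", n_codon,
         " codons but protein has ", n_aa, " residues", call. = FALSE)
  }
  tr <- translate_cds(cds)
  if (tr != protein) {
    pos <- which(strsplit(tr, "")[[1]] != strsplit(protein, "")[[1]])[1]
    if (substr(tr, pos, pos) == "*")
      stop("gene ", gene_id, ": internal stop codon at residue ", pos,
           call. = FALSE)
    stop("gene ", gene_id, ": translation mismatch at residue ", pos,
         " (CDS codes ", substr(tr, pos, pos), ", protein has ",
         substr(protein, pos, pos), ")", call. = FALSE)
  }
  structure(list(gene_id = gene_id, protein = protein, cds = cds,
                 has_stop = has_stop),
            class = "coding_gene")
}

#' Translate a CDS with the standard genetic code
#'
#' @param cds Nucleotide string (length a multiple of 3, A/C/G/T).
#' @return Amino-acid string; stop codons render as `*`.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa))
    stop("invalid codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  paste(aa, collapse = "")
}

#' Load a paired protein/CDS FASTA database
#'
#' Reads a protein FASTA and a CDS FASTA whose identifiers must match
#' one-to-one, validates translation consistency record by record, and
#' returns the database used for peptide localization and codon lookup.
#'
#' @param protein_path,cds_path FASTA file paths.
#' @return A list of class `coding_db`: one [coding_gene()] per record,
#'   named by `gene_id`, in protein-file order.
#' @export
read_paired_fasta <- function(protein_path, cds_path) {
  prot <- Biostrings::readAAStringSet(protein_path)
  cds <- Biostrings::readDNAStringSet(cds_path)
  pid <- sub("\\s.*$", "", names(prot))
  cid <- sub("\\s.*$", "", names(cds))
  if (anyDuplicated(pid))
    stop("duplicate protein FASTA identifier(s): ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cid))
    stop("duplicate CDS FASTA identifier(s): ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "), call. = FALSE)
  only_p <- setdiff(pid, cid)
  only_c <- setdiff(cid, pid)
  if (length(only_p) || length(only_c))
    stop("identifiers present in one file only: ",
         paste(c(only_p, only_c), collapse = ", "), call. = FALSE)
  genes <- lapply(seq_along(pid), function(i) {
    coding_gene(pid[i], as.character(prot[[i]]),
                as.character(cds[[match(pid[i], cid)]]))
  })
  names(genes) <- pid
  structure(genes, class = "coding_db")
}

#' Build a database from in-memory sequences
#'
#' @param gene_ids,proteins,cds Parallel character vectors.
#' @return A `coding_db`.
#' @export
coding_db <- function(gene_ids, proteins, cds) {
  stopifnot(length(gene_ids) == length(proteins),
            length(proteins) == length(cds))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_id(s)", call. = FALSE)
  genes <- Map(coding_gene, gene_ids, proteins, cds)
  names(genes) <- gene_ids
  structure(genes, class = "coding_db")
}

#' @export
print.coding_db <- function(x, ...) {
  cat("coding_db with", length(x), "genes;",
      sum(vapply(x, function(g) nchar(g$protein), 0L)), "residues\n")
  invisible(x)
}

#' In-silico Lys-C digestion
#'
#' Cleaves strictly C-terminal to every lysine, including before proline
#' (Lys-C, unlike trypsin, cleaves K|P). With `max_missed > 0` all
#' concatenations of up to `max_missed + 1` adjacent fragments are also
#' returned.
#'
#' @param protein Protein sequence.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return data.frame with columns `peptide` and `start` (0-based offset
#'   into the protein), ordered by start then length.
#' @export
digest_lysC <- function(protein, max_missed = 0L) {
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  stopifnot(max_missed >= 0L)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cut_after <- which(aa == "K")
  bounds <- unique(c(0L, cut_after, length(aa)))  # 0-based fragment bounds
  n_frag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      out[[length(out) + 1L]] <- list(
        peptide = substr(protein, bounds[i] + 1L, bounds[j + 1L]),
        start = bounds[i]
      )
    }
  }
  df <- data.frame(
    peptide = vapply(out, `[[`, "", "peptide"),
    start = vapply(out, `[[`, 0L, "start"),
    stringsAsFactors = FALSE
  )
  df[order(df$start, nchar(df$peptide)), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

# Concatenate all proteins into one search string with a separator that
# cannot occur in a peptide, plus offset bookkeeping for mapping matches
# back to (gene, position).
.db_search_string <- function(db) {
  prots <- vapply(db, function(g) g$protein, "")
  big <- paste(prots, collapse = "-")
  starts <- c(0L, cumsum(nchar(prots) + 1L))[seq_along(prots)]  # 0-based
  list(big = big, gene_ids = names(db), starts = starts,
       lens = nchar(prots))
}

#' Locate peptides in the protein database
#'
#' Finds every exact occurrence of each wild-type (pre-substitution)
#' peptide sequence across all proteins, in deterministic
#' (gene_id, start) order. Occurrences are substring matches; they need
#' not respect digestion boundaries, since the purpose is to detect
#' localization ambiguity.
#'
#' @param base_sequences Character vector of peptide sequences.
#' @param db A `coding_db`.
#' @return data.frame with columns `peptide`, `gene_id`, `start`
#'   (0-based residue offset). Peptides with no match contribute no rows.
#' @export
locate_peptides <- function(base_sequences, db) {
  ss <- .db_search_string(db)
  seqs <- unique(base_sequences)
  res <- lapply(seqs, function(p) {
    if (!nzchar(p)) return(NULL)
    m <- gregexpr(p, ss$big, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos0 <- as.integer(m) - 1L                      # 0-based in big string
    gi <- findInterval(pos0, ss$starts)             # gene index
    start <- pos0 - ss$starts[gi]
    keep <- start + nchar(p) <= ss$lens[gi]         # no separator crossing
    if (!any(keep)) return(NULL)
    data.frame(peptide = p, gene_id = ss$gene_ids[gi[keep]],
               start = start[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(peptide = character(), gene_id = character(),
                      start = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$peptide, out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname locate_peptides
#' @param base_sequence A single peptide sequence.
#' @export
locate_peptide <- function(base_sequence, db) {
  locate_peptides(base_sequence, db)
}

#' Codon at a protein residue position
#'
#' @param gene A [coding_gene()].
#' @param residue_index 0-based residue index into the protein.
#' @return Three-letter codon (DNA alphabet) coding that residue.
#' @export
codon_at <- function(gene, residue_index) {
  stopifnot(inherits(gene, "coding_gene"))
  n <- nchar(gene$protein)
  if (any(residue_index < 0L | residue_index >= n))
    stop("residue_index out of range [0, ", n - 1L, "] for gene ",
         gene$gene_id, call. = FALSE)
  substring(gene$cds, 3L * residue_index + 1L, 3L * residue_index + 3L)
}

#' Write a peptide-location report
#'
#' TSV with 1-based start positions (rendered coordinates are 1-based;
#' in-memory coordinates are 0-based).
#'
#' @param locations data.frame from [locate_peptides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_location_report <- function(locations, path) {
  out <- locations
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
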