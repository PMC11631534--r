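# Fixture builders shared across test files. All fixtures are built in
# code; nothing binary on disk.

# The toy gene used throughout: MKVTSK with one codon per residue plus a
# stop; residue 2 (0-based) is V coded GTT, residue 3 is T coded ACC.
toy_gene <- function() {
  coding_gene("gene1", "MKVTSK", "ATGAAAGTTACCTCTAAATAA")
}

toy_db <- function() {
  coding_db(
    c("gene1", "gene2"),
    c("MKVTSK", "MKAAAK"),
    c("ATGAAAGTTACCTCTAAATAA", "ATGAAAGCTGCCGCAAAATAA")
  )
}

# Build a unique_peptides table from plain vectors; sub_positions given
# as a list of 0-based integer vectors.
make_unique_peptides <- function(base_sequence, sub_positions = NULL,
                                 sub_from = "", sub_to = "",
                                 psm_count = 1L, best_q = 0) {
  n <- length(base_sequence)
  if (is.null(sub_positions))
    sub_positions <- replicate(n, integer(0), simplify = FALSE)
  up <- data.frame(base_sequence = base_sequence,
                   sub_from = rep_len(sub_from, n),
                   sub_to = rep_len(sub_to, n),
                   stringsAsFactors = FALSE)
  up$sub_positions <- sub_positions
  up$is_substituted <- lengths(sub_positions) > 0L
  up$sub_from[!up$is_substituted] <- ""
  up$sub_to[!up$is_substituted] <- ""
  up$psm_count <- rep_len(as.integer(psm_count), n)
  up$best_q <- rep_len(best_q, n)
  class(up) <- c("unique_peptides", class(up))
  up
}

# Write a PSM table file from row lists (positions 1-based, as in the
# dialect).
write_psm_fixture <- function(path, rows) {
  header <- paste(c("spectrum_id", "base_sequence", "sub_positions",
                    "sub_from", "sub_to", "charge", "calc_mass",
                    "obs_mass", "score", "is_decoy"), collapse = "\t")
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(c(header, lines), path)
  path
}

# A valid 1-substitution PSM row for the toy peptide VTSK (V at in-file
# position 1).
toy_psm_row <- function(id = "s1", seq = "VTSK", pos = "1", from = "V",
                        to = "S", score = 10, decoy = 0) {
  m <- peptide_mass(seq) + (if (nzchar(pos)) substitution_delta(from, to)
                            else 0)
  c(id, seq, pos, if (nzchar(pos)) from else "",
    if (nzchar(pos)) to else "", 2, sprintf("%.6f", m),
    sprintf("%.6f", m), score, decoy)
}

# Independent elemental-composition oracle for residue masses.
elemental_residue_masses <- function() {
  iso <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),
    K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1),
    Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  vapply(comp, function(x) sum(iso[names(x)] * x), 0)
}

# Independent two-sided Fisher p by exhaustive hypergeometric
# enumeration (point-probability rule).
enumerate_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  dens <- dhyper(supp, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-12)])
}
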