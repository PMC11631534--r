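# PSM table I/O, target-decoy q-values, FDR filtering and collapse to
# unique peptides. This stage stands in for a search-engine/Percolator
# pipeline: scores are consumed as given and a transparent target-decoy
# estimator assigns q-values.

.PSM_COLUMNS <- c("spectrum_id", "base_sequence", "sub_positions",
                  "sub_from", "sub_to", "charge", "calc_mass", "obs_mass",
                  "score", "is_decoy")

#' Read a PSM table
#'
#' Tab-separated, UTF-8, header row, columns exactly: `spectrum_id`,
#' `base_sequence` (wild-type sequence), `sub_positions` (semicolon-joined
#' 1-based positions of substituted residues; empty for a wild-type
#' peptide), `sub_from`, `sub_to`, `charge`, `calc_mass`, `obs_mass`,
#' `score`, `is_decoy` (0/1). Positions are converted to 0-based in
#' memory.
#'
#' Structural violations (more than two substituted sites, a substituted
#' position not carrying the origin residue, positions out of range, or a
#' precursor mass outside `tol_ppm`) reject the offending row; rejected
#' rows are reported in the `"rejected"` attribute and via a warning.
#'
#' @param path File path.
#' @param tol_ppm Precursor tolerance for the calc/obs mass check.
#' @param max_sites Maximum substituted positions per peptide (search
#'   design allows at most 2 of each variable modification).
#' @return data.frame of PSMs with `sub_positions` as a list column of
#'   0-based integer vectors and a `q_value` column initialised to NA.
#' @export
read_psm_table <- function(path, tol_ppm = 20, max_sites = 2L) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.PSM_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("PSM table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, .PSM_COLUMNS]
  psms <- data.frame(
    spectrum_id = raw$spectrum_id,
    base_sequence = toupper(raw$base_sequence),
    sub_from = raw$sub_from,
    sub_to = raw$sub_to,
    charge = as.integer(raw$charge),
    calc_mass = as.numeric(raw$calc_mass),
    obs_mass = as.numeric(raw$obs_mass),
    score = as.numeric(raw$score),
    is_decoy = as.integer(raw$is_decoy) == 1L,
    stringsAsFactors = FALSE
  )
  psms$sub_positions <- lapply(raw$sub_positions, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]]) - 1L
  })
  psms$q_value <- NA_real_
  validate_psms(psms, tol_ppm = tol_ppm, max_sites = max_sites)
}

#' Validate PSM structural invariants
#'
#' @param psms PSM data.frame (as from [read_psm_table()]).
#' @inheritParams read_psm_table
#' @return The valid subset; rejected rows (with a `reason` column) are
#'   attached as attribute `"rejected"`.
#' @export
validate_psms <- function(psms, tol_ppm = 20, max_sites = 2L) {
  reason <- character(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    pos <- psms$sub_positions[[i]]
    seq <- psms$base_sequence[i]
    if (length(pos) > max_sites) {
      reason[i] <- sprintf("more than %d substituted positions", max_sites)
    } else if (length(pos)) {
      if (!nzchar(psms$sub_from[i]) || !nzchar(psms$sub_to[i])) {
        reason[i] <- "substituted row lacks sub_from/sub_to"
      } else if (any(pos < 0L | pos >= nchar(seq))) {
        reason[i] <- "substituted position out of sequence range"
      } else if (any(substring(seq, pos + 1L, pos + 1L) != psms$sub_from[i])) {
        reason[i] <- "residue at substituted position differs from sub_from"
      }
    }
    if (!nzchar(reason[i]) && is.finite(psms$calc_mass[i]) &&
        is.finite(psms$obs_mass[i]) &&
        !within_ppm(psms$obs_mass[i], psms$calc_mass[i], tol_ppm)) {
      reason[i] <- sprintf("precursor mass outside %g ppm", tol_ppm)
    }
  }
  bad <- nzchar(reason)
  if (any(bad))
    warning(sum(bad), " PSM row(s) rejected (see attr(, 'rejected'))",
            call. = FALSE)
  rejected <- psms[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  out <- psms[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Target-decoy q-values
#'
#' For every score threshold `s`, `FDR(s) = #{decoys with score >= s} /
#' max(1, #{targets with score >= s})` (capped at 1); a target's q-value
#' is the minimum FDR over all thresholds at or below its score, so q is
#' nonincreasing in score. Decoys receive the q-value of the nearest
#' target threshold with score <= theirs (1 if none). Ties in score count
#' decoys before targets, which is the conservative convention.
#'
#' @param psms PSM data.frame with `score` and `is_decoy`.
#' @return `psms` with `q_value` filled in.
#' @export
compute_qvalues <- function(psms) {
  if (!any(!psms$is_decoy)) stop("no target PSMs", call. = FALSE)
  t_scores <- psms$score[!psms$is_decoy]
  d_scores <- psms$score[psms$is_decoy]
  ord <- order(t_scores, decreasing = TRUE)
  s <- t_scores[ord]
  t_asc <- rev(s)
  d_asc <- sort(d_scores)
  n_t <- length(t_scores)
  # counts at each target threshold; ties among targets share the count;
  # ties between a decoy and a target count the decoy (>= comparison)
  n_t_ge <- n_t - findInterval(s, t_asc, left.open = TRUE)
  n_d_ge <- length(d_asc) - findInterval(s, d_asc, left.open = TRUE)
  fdr <- pmin(1, n_d_ge / pmax(1L, n_t_ge))
  q_sorted <- rev(cummin(rev(fdr)))
  q_t <- numeric(n_t)
  q_t[ord] <- q_sorted
  q <- numeric(nrow(psms))
  q[!psms$is_decoy] <- q_t
  if (any(psms$is_decoy)) {
    # nearest target threshold at or below the decoy score
    idx <- n_t - findInterval(d_scores, t_asc) + 1L
    qd <- ifelse(idx > n_t, 1, q_sorted[pmin(idx, n_t)])
    q[psms$is_decoy] <- qd
  }
  psms$q_value <- q
  psms
}

#' Filter PSMs at an FDR threshold
#'
#' Retains target PSMs with `q_value <= threshold`; decoys are removed.
#'
#' @param psms PSMs with q-values computed.
#' @param threshold FDR threshold in (0, 1]; the search design this
#'   package mirrors uses 0.01 at the PSM level.
#' @return The retained subset.
#' @export
filter_fdr <- function(psms, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (nrow(psms) == 0L) return(psms)
  if (all(is.na(psms$q_value)) && nrow(psms) > 0L)
    stop("q-values not computed; run compute_qvalues() first", call. = FALSE)
  out <- psms[!psms$is_decoy & psms$q_value <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# identity key of a (possibly substituted) peptide form
.peptide_key <- function(base_sequence, sub_positions, sub_from, sub_to) {
  pos <- vapply(sub_positions, function(p)
    paste(sort(p), collapse = ";"), "")
  paste(base_sequence, pos, ifelse(pos == "", "", sub_from),
        ifelse(pos == "", "", sub_to), sep = "|")
}

#' Collapse filtered PSMs to unique peptides
#'
#' Identity is the tuple (base_sequence, substituted positions, sub_from,
#' sub_to): the wild-type and substituted forms of one base sequence are
#' distinct unique peptides, as are the same substitution at different
#' positions.
#'
#' @param psms Filtered target PSMs.
#' @return data.frame of class `unique_peptides`: `base_sequence`,
#'   `sub_positions` (list column, 0-based), `sub_from`, `sub_to`,
#'   `is_substituted`, `psm_count`, `best_q`.
#' @export
collapse_to_unique <- function(psms) {
  key <- .peptide_key(psms$base_sequence, psms$sub_positions,
                      psms$sub_from, psms$sub_to)
  first <- !duplicated(key)
  idx <- which(first)
  counts <- table(key)
  best_q <- tapply(psms$q_value, key, min)
  out <- data.frame(
    base_sequence = psms$base_sequence[idx],
    sub_from = psms$sub_from[idx],
    sub_to = psms$sub_to[idx],
    stringsAsFactors = FALSE
  )
  out$sub_positions <- psms$sub_positions[idx]
  out$is_substituted <- lengths(out$sub_positions) > 0L
  k <- key[idx]
  out$psm_count <- as.integer(counts[k])
  out$best_q <- as.numeric(best_q[k])
  out <- out[order(out$base_sequence, vapply(out$sub_positions, function(p)
    paste(sort(p), collapse = ";"), "")), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unique_peptides", class(out))
  out
}

#' Write a PSM table in the package dialect
#'
#' Inverse of [read_psm_table()]: positions rendered 1-based,
#' semicolon-joined; `is_decoy` as 0/1.
#'
#' @param psms PSM data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- data.frame(
    spectrum_id = psms$spectrum_id,
    base_sequence = psms$base_sequence,
    sub_positions = vapply(psms$sub_positions, function(p)
      paste(sort(p) + 1L, collapse = ";"), ""),
    sub_from = psms$sub_from,
    sub_to = psms$sub_to,
    charge = psms$charge,
    calc_mass = sprintf("%.6f", psms$calc_mass),
    obs_mass = sprintf("%.6f", psms$obs_mass),
    score = sprintf("%.6f", psms$score),
    is_decoy = as.integer(psms$is_decoy),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
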