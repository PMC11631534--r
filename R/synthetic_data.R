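# Synthetic-data generators emulating the study's data-generating
# process: a coding proteome, Lys-C PSM tables with a ground-truth
# substitution ledger, and phenotype (survival, count) tables. Every
# generator is a deterministic function of its seed.

#' Simulation specification
#'
#' Defaults emulate the whole-proteome Lys-C experiment this package
#' analyses: a proteome large enough to supply >= 5,000 origin-residue
#' events per threonine codon, serine misincorporation at per-codon
#' rates of order 0.01-1%, wild-type siblings observed with high
#' probability, and reversed-sequence decoys with a null score
#' distribution well separated from targets.
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param n_genes Number of genes.
#' @param len_shape,len_scale Gamma parameters of protein length
#'   (default mean ~350 aa); lengths are clamped to >= 60 aa.
#' @param codon_weights Named weights over the 61 sense codons used to
#'   draw coding sequences (default uniform).
#' @param substitution A [substitution_spec()] (default T->S).
#' @param anticodon Variant tRNA anticodon (default AGU, the
#'   threonine-decoding serine tRNA variant).
#' @param per_codon_rates Named per-site substitution probabilities for
#'   the codons of the origin residue. Default
#'   `c(ACT = 0.01, ACC = 0.005, ACA = 0, ACG = 0)`.
#' @param detection_prob Probability that a peptide's wild-type form is
#'   observed (the sibling detection model).
#' @param decoy_fraction Decoy PSMs as a fraction of target rows.
#' @param score_target,score_decoy Mean of the Gaussian (sd 1) score
#'   distributions.
#' @param ppm_jitter Half-width (ppm) of the uniform observed-mass error.
#' @param min_len,max_len Retained peptide length range (residues).
#' @param extra_psm_lambda Poisson mean of extra spectral replicates per
#'   observed wild-type peptide.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 1500L,
                            len_shape = 12, len_scale = 29,
                            codon_weights = NULL,
                            substitution = substitution_spec("T", "S"),
                            anticodon = "AGU",
                            per_codon_rates = c(ACT = 0.01, ACC = 0.005,
                                                ACA = 0, ACG = 0),
                            detection_prob = 0.95,
                            decoy_fraction = 0.2,
                            score_target = 6, score_decoy = 0,
                            ppm_jitter = 5,
                            min_len = 5L, max_len = 60L,
                            extra_psm_lambda = 0.25) {
  gc <- Biostrings::GENETIC_CODE
  sense <- sort(names(gc)[gc != "*"])
  if (is.null(codon_weights))
    codon_weights <- stats::setNames(rep(1, length(sense)), sense)
  if (!all(names(codon_weights) %in% sense) || any(codon_weights < 0) ||
      sum(codon_weights) <= 0)
    stop("codon_weights must be nonnegative weights on sense codons",
         call. = FALSE)
  stopifnot(inherits(substitution, "substitution_spec"))
  expected <- codons_for_residue(substitution$from_aa)
  if (!all(names(per_codon_rates) %in% expected))
    stop("per_codon_rates names must be codons of ",
         substitution$from_aa, call. = FALSE)
  rates <- stats::setNames(rep(0, length(expected)), expected)
  rates[names(per_codon_rates)] <- per_codon_rates
  if (any(rates < 0 | rates > 1))
    stop("rates must be probabilities", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    len_shape = len_shape, len_scale = len_scale,
    codon_weights = codon_weights, substitution = substitution,
    anticodon = anticodon, per_codon_rates = rates,
    detection_prob = detection_prob, decoy_fraction = decoy_fraction,
    score_target = score_target, score_decoy = score_decoy,
    ppm_jitter = ppm_jitter, min_len = as.integer(min_len),
    max_len = as.integer(max_len), extra_psm_lambda = extra_psm_lambda
  ), class = "simulation_spec")
}

#' Generate a synthetic coding proteome
#'
#' Draws codons independently from `codon_weights` (a start codon is not
#' forced; the database layer does not require one), appends a TAA stop,
#' and pairs each CDS with its translation.
#'
#' @param spec A [simulation_spec()].
#' @return A `coding_db`.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  gc <- Biostrings::GENETIC_CODE
  cods <- names(spec$codon_weights)
  lens <- pmax(60L, round(stats::rgamma(spec$n_genes, shape = spec$len_shape,
                                        scale = spec$len_scale)))
  ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  cds <- vapply(lens, function(n) {
    paste0(paste(sample(cods, n, replace = TRUE,
                        prob = spec$codon_weights), collapse = ""), "TAA")
  }, "")
  prot <- vapply(cds, function(x)
    translate_cds(substr(x, 1L, nchar(x) - 3L)), "", USE.NAMES = FALSE)
  coding_db(ids, prot, cds)
}

#' Write a database as paired FASTA files
#'
#' @param db A `coding_db`.
#' @param protein_path,cds_path Output FASTA paths.
#' @return Invisibly, the two paths.
#' @export
write_paired_fasta <- function(db, protein_path, cds_path) {
  aa <- Biostrings::AAStringSet(vapply(db, function(g) g$protein, ""))
  nt <- Biostrings::DNAStringSet(vapply(db, function(g)
    paste0(g$cds, if (g$has_stop) "TAA" else ""), ""))
  names(aa) <- names(nt) <- names(db)
  Biostrings::writeXStringSet(aa, protein_path)
  Biostrings::writeXStringSet(nt, cds_path)
  invisible(c(protein = protein_path, cds = cds_path))
}

#' Generate a PSM table with a ground-truth ledger
#'
#' Digests every protein with Lys-C (no missed cleavages), retains
#' peptides in the configured length range, substitutes each origin
#' residue site independently with its codon's rate (one substituted PSM
#' per event), emits the wild-type form of each peptide with probability
#' `detection_prob` (plus Poisson spectral replicates), and appends
#' reversed-sequence decoy PSMs with null scores.
#'
#' @param spec A [simulation_spec()].
#' @param db A `coding_db`, typically from [generate_proteome()].
#' @return List with `psms` (PSM data.frame in the package dialect, with
#'   `sub_positions` as a 0-based list column) and `ledger` (per-codon
#'   ground truth: `codon`, `rate`, `n_sites`, `n_sub_events`,
#'   `n_sites_wt_observed`, `n_sub_with_sibling`).
#' @export
generate_psms <- function(spec, db) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(db, "coding_db"))
  set.seed(spec$seed + 1L)
  sub <- spec$substitution
  origin <- sub$from_aa
  rates <- spec$per_codon_rates

  peps <- do.call(rbind, lapply(db, function(g) {
    d <- digest_lysC(g$protein, max_missed = 0L)
    d <- d[nchar(d$peptide) >= spec$min_len &
             nchar(d$peptide) <= spec$max_len, , drop = FALSE]
    if (nrow(d)) d$gene_id <- g$gene_id
    d
  }))
  if (is.null(peps) || nrow(peps) == 0L) stop("empty digest", call. = FALSE)
  rownames(peps) <- NULL

  # site-level bookkeeping, vectorized over all origin-residue sites
  wt_seen <- stats::runif(nrow(peps)) < spec$detection_prob
  pos_list <- gregexpr(origin, peps$peptide, fixed = TRUE)
  n_sites_per_pep <- vapply(pos_list, function(p)
    if (p[1] == -1L) 0L else length(p), 0L)
  site_pep <- rep(seq_len(nrow(peps)), n_sites_per_pep)
  site_pos0 <- unlist(lapply(pos_list, function(p)
    if (p[1] == -1L) integer(0) else as.integer(p) - 1L), use.names = FALSE)
  cds_by_gene <- vapply(db, `[[`, "", "cds")
  ri <- peps$start[site_pep] + site_pos0
  site_codon <- substring(cds_by_gene[peps$gene_id[site_pep]],
                          3L * ri + 1L, 3L * ri + 3L)
  hit <- stats::runif(length(site_codon)) < rates[site_codon]

  cnt <- function(codons) {
    tab <- table(factor(codons, levels = names(rates)))
    as.integer(tab)
  }
  led <- data.frame(
    codon = names(rates), rate = as.numeric(rates),
    n_sites = cnt(site_codon),
    n_sub_events = cnt(site_codon[hit]),
    n_sites_wt_observed = cnt(site_codon[wt_seen[site_pep]]),
    n_sub_with_sibling = cnt(site_codon[hit & wt_seen[site_pep]]),
    stringsAsFactors = FALSE
  )

  wt_pep <- peps$peptide[wt_seen]
  wt_n <- 1L + stats::rpois(length(wt_pep), spec$extra_psm_lambda)
  wt_seq <- rep(wt_pep, wt_n)
  sub_pep <- peps$peptide[site_pep[hit]]
  sub_pos <- site_pos0[hit]

  aa_mass <- residue_mass_table()
  mk_mass <- function(seqs, nsub) {
    vapply(seqs, function(s)
      sum(aa_mass$residues[strsplit(s, "")[[1]]]), 0,
      USE.NAMES = FALSE) + aa_mass$water + nsub * sub$delta
  }

  n_t <- length(wt_seq) + length(sub_pep)
  n_d <- round(spec$decoy_fraction * n_t)
  decoy_pool <- unlist(lapply(db, function(g) {
    rp <- paste(rev(strsplit(g$protein, "")[[1]]), collapse = "")
    d <- digest_lysC(rp, max_missed = 0L)
    d$peptide[nchar(d$peptide) >= spec$min_len &
                nchar(d$peptide) <= spec$max_len]
  }), use.names = FALSE)
  decoy_seq <- if (n_d > 0L) sample(decoy_pool, n_d, replace = TRUE)
               else character(0)

  seqs <- c(wt_seq, sub_pep, decoy_seq)
  nsub <- c(rep(0L, length(wt_seq)), rep(1L, length(sub_pep)),
            rep(0L, length(decoy_seq)))
  calc <- mk_mass(seqs, nsub)
  obs <- calc * (1 + stats::runif(length(calc), -spec$ppm_jitter,
                                  spec$ppm_jitter) * 1e-6)
  is_decoy <- c(rep(FALSE, n_t), rep(TRUE, length(decoy_seq)))
  score <- ifelse(is_decoy, stats::rnorm(length(seqs), spec$score_decoy, 1),
                  stats::rnorm(length(seqs), spec$score_target, 1))
  psms <- data.frame(
    spectrum_id = sprintf("scan%06d", seq_along(seqs)),
    base_sequence = seqs,
    sub_from = c(rep("", length(wt_seq)), rep(origin, length(sub_pep)),
                 rep("", length(decoy_seq))),
    sub_to = c(rep("", length(wt_seq)), rep(sub$to_aa, length(sub_pep)),
               rep("", length(decoy_seq))),
    charge = 2L,
    calc_mass = calc, obs_mass = obs, score = score, is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
  psms$sub_positions <- c(replicate(length(wt_seq), integer(0),
                                    simplify = FALSE),
                          as.list(as.integer(sub_pos)),
                          replicate(length(decoy_seq), integer(0),
                                    simplify = FALSE))
  psms$q_value <- NA_real_
  rownames(led) <- NULL
  list(psms = psms, ledger = led)
}

#' Generate a two-group survival table
#'
#' Exponential death times discretized to 3-day inspection intervals
#' (the food-transfer schedule), with independent escape-type censoring:
#' with probability `censor_rate` a subject is instead censored at an
#' inspection day drawn uniformly at or before its death day.
#'
#' @param n_per_group Subjects per group (length 2 or scalar).
#' @param hazards Named numeric vector of 2 exponential hazards (per
#'   day); names are group labels.
#' @param censor_rate Probability of censoring in \[0, 1\].
#' @param seed Integer seed.
#' @return An [event_table()].
#' @export
generate_survival <- function(n_per_group, hazards, censor_rate = 0.05,
                              seed = 1L) {
  if (any(hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must be in [0, 1]", call. = FALSE)
  if (is.null(names(hazards)))
    names(hazards) <- paste0("group", seq_along(hazards))
  n_per_group <- rep(n_per_group, length.out = length(hazards))
  set.seed(seed)
  rows <- lapply(seq_along(hazards), function(g) {
    n <- n_per_group[g]
    t_death <- stats::rexp(n, rate = hazards[g])
    day <- pmax(3, 3 * ceiling(t_death / 3))
    cens <- stats::runif(n) < censor_rate
    day_c <- vapply(day / 3, function(k) 3 * sample.int(k, 1L), 0)
    data.frame(
      subject_id = sprintf("%s_%03d", names(hazards)[g], seq_len(n)),
      group = names(hazards)[g],
      time = ifelse(cens, day_c, day),
      status = as.integer(!cens),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  event_table(df$subject_id, df$group, df$time, df$status)
}

#' Generate a 2x2 outcome count table
#'
#' Binomial success counts per group (e.g. deformity or climbing
#' scoring).
#'
#' @param p_per_group Success probabilities, length 2.
#' @param n_per_group Trials per group, length 2 (or scalar).
#' @param seed Integer seed.
#' @return 2x2 integer matrix (rows = groups, columns =
#'   success/failure).
#' @export
generate_counts <- function(p_per_group, n_per_group, seed = 1L) {
  if (any(p_per_group < 0 | p_per_group > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  n_per_group <- rep(n_per_group, length.out = length(p_per_group))
  set.seed(seed)
  k <- stats::rbinom(length(p_per_group), n_per_group, p_per_group)
  m <- cbind(success = k, failure = n_per_group - k)
  rownames(m) <- names(p_per_group) %||% paste0("group", seq_along(k))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
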