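# Sibling rule, residue-level frequency, unique localization, per-codon
# counting and decoding classification.

test_that("sibling filter keeps substituted peptides only with an observed wild-type form", {
  up <- make_unique_peptides(
    c("VTSK", "VTSK", "AVAK"),
    sub_positions = list(0L, integer(0), 1L),
    sub_from = "V", sub_to = "S"
  )
  kept <- sibling_filter(up)
  expect_equal(kept$base_sequence, "VTSK")  # AVAK(V2S) has no sibling
  # wild-type-only input yields nothing
  expect_equal(nrow(sibling_filter(make_unique_peptides(c("VTSK", "MK")))), 0L)
})

test_that("residue-level frequency is numerator over origin-containing peptides", {
  # 2 substituted peptides (siblings observed) among a denominator of 200
  wt_seqs <- c(paste0("AV", sprintf("%03d", 1:196), "K"))  # invalid residues?
  # build 196 distinct V-containing wild-type peptides from a clean alphabet
  combos <- expand.grid(a = c("A", "G", "L", "M", "F", "Y"),
                        b = c("A", "G", "L", "M", "F", "Y"),
                        c = c("A", "G", "L", "M", "F", "Y"))
  wt_seqs <- paste0("V", combos$a, combos$b, combos$c, "K")[1:196]
  up <- make_unique_peptides(
    c("VTSK", "AVAK", "VTSK", "AVAK", wt_seqs),
    sub_positions = c(list(0L, 1L), replicate(198, integer(0),
                                              simplify = FALSE)),
    sub_from = "V", sub_to = "S"
  )
  res <- mistranslation_frequency(up, substitution_spec("V", "S"))
  expect_equal(res$n_mistranslated, 2L)
  expect_equal(res$n_total, 200L)
  expect_equal(res$frequency_pct, 1.0)
})

test_that("no substituted peptides gives 0%, no origin peptides gives NA", {
  up <- make_unique_peptides(c("VTSK", "AVAK"))
  expect_equal(
    mistranslation_frequency(up, substitution_spec("V", "S"))$frequency_pct, 0)
  up2 <- make_unique_peptides(c("MGK", "AGK"))
  expect_warning(
    res <- mistranslation_frequency(up2, substitution_spec("V", "S")),
    "undefined")
  expect_true(is.na(res$frequency_pct))
})

test_that("spectral-count mode weights peptides by psm_count", {
  up <- make_unique_peptides(
    c("VTSK", "VTSK"), sub_positions = list(0L, integer(0)),
    sub_from = "V", sub_to = "S", psm_count = c(1L, 3L)
  )
  res_u <- mistranslation_frequency(up, substitution_spec("V", "S"))
  res_p <- mistranslation_frequency(up, substitution_spec("V", "S"),
                                    count = "psm")
  expect_equal(res_u$frequency_pct, 100 * 1 / 2)
  expect_equal(res_p$frequency_pct, 100 * 1 / 4)
})

test_that("unique-localization keeps single-site, uniquely mapping peptides", {
  db2 <- coding_db(c("a", "b"),
                   c("MKVTSK", "AVTSKA"),
                   c("ATGAAAGTTACCTCTAAA", "GCTGTTACCTCTAAAGCT"))
  subs <- make_unique_peptides(
    c("MKVTSK", "VTSK", "MKVTSK"),
    sub_positions = list(2L, 0L, c(2L, 3L)),
    sub_from = "V", sub_to = "S"
  )
  subs$sub_from[3] <- "V"  # two-site row
  kept <- unique_localization_filter(subs, db2)
  # VTSK occurs in both genes (dropped); the two-site row is dropped;
  # MKVTSK maps uniquely to gene a
  expect_equal(kept$base_sequence, "MKVTSK")
  expect_equal(kept$gene_id, "a")
  expect_equal(kept$start, 0L)
})

test_that("per-codon frequency matches a constructed single-codon fixture", {
  # 33 distinct wild-type peptides with 3 GTT-coded valines each plus the
  # substituted peptide's sibling: 99 wild-type V events at GTT once the
  # substituted sibling (3 V) is included; 1 substituted event.
  fill <- expand.grid(a = c("A", "G", "L", "M", "F", "Y"),
                      b = c("A", "G", "L", "M", "F", "Y"))
  mk_prot <- function(i) paste0("V", fill$a[i], "V", fill$b[i], "VK")
  prots <- vapply(2:33, mk_prot, "")  # row 1 would duplicate VAVAVK
  prots <- c(prots, "VAVAVK")  # the substituted peptide's base sequence
  aa2codon <- function(a)
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  mk_cds <- function(p) {
    aa <- strsplit(p, "")[[1]]
    paste(vapply(aa, function(x) if (x == "V") "GTT" else aa2codon(x), ""),
          collapse = "")
  }
  db <- coding_db(sprintf("g%02d", seq_along(prots)), prots,
                  vapply(prots, mk_cds, "", USE.NAMES = FALSE))
  up <- make_unique_peptides(
    c(prots, "VAVAVK"),
    sub_positions = c(replicate(33, integer(0), simplify = FALSE), list(0L)),
    sub_from = "V", sub_to = "S"
  )
  cf <- per_codon_frequency(up, db, substitution_spec("V", "S"),
                            anticodon = "AAC")
  gtt <- cf[cf$codon == "GTT", ]
  expect_equal(gtt$n_sub_events, 1)
  expect_equal(gtt$n_wt_events, 99)
  expect_equal(gtt$frequency_pct, 1.0)
  expect_true(all(cf$frequency_pct[cf$codon != "GTT"] == 0))
  # event-weighted mean equals the event-level overall frequency
  ov <- attr(cf, "overall")
  tot <- cf$n_sub_events + cf$n_wt_events
  expect_equal(sum(cf$frequency_pct * tot) / sum(tot),
               unname(ov["frequency_pct"]), tolerance = 1e-12)
})

test_that("per-codon frequency is all zero without substituted peptides", {
  db <- toy_db()
  up <- make_unique_peptides(c("VTSK", "MK"))
  cf <- per_codon_frequency(up, db, substitution_spec("V", "S"),
                            anticodon = "AAC")
  expect_true(all(cf$frequency_pct == 0))
  expect_equal(sort(cf$codon), c("GTA", "GTC", "GTG", "GTT"))
})

test_that("decoding classes match the hand-built truth table", {
  # threonine-decoding serine variant (anticodon AGU) over the ACN box
  expect_equal(classify_decoding("AGU", "ACU"), "watson_crick")
  expect_equal(classify_decoding("AGU", "ACC"), "wobble_I34")
  expect_equal(classify_decoding("AGU", "ACA"), "wobble_I34")
  expect_equal(classify_decoding("AGU", "ACG"), "mismatch_3prime")
  # valine-decoding serine variant (anticodon AAC) over the GUN box
  expect_equal(classify_decoding("AAC", "GUU"), "watson_crick")
  expect_equal(classify_decoding("AAC", "GUC"), "wobble_I34")
  expect_equal(classify_decoding("AAC", "GUA"), "wobble_I34")
  expect_equal(classify_decoding("AAC", "GUG"), "mismatch_3prime")
  # G34 and U34 wobble
  expect_equal(classify_decoding("GGU", "ACU"), "wobble_GU")
  expect_equal(classify_decoding("UGU", "ACG"), "wobble_GU")
  expect_equal(classify_decoding("GGU", "ACC"), "watson_crick")
  expect_equal(classify_decoding("UGU", "ACA"), "watson_crick")
  # mispairs at codon positions 1/2 are 'other'
  expect_equal(classify_decoding("AGU", "GCU"), "other")
  expect_equal(classify_decoding("AGU", "AAU"), "other")
  expect_equal(classify_decoding("AAC", "ACU"), "other")
  # DNA alphabet accepted
  expect_equal(classify_decoding("AGT", "ACT"), "watson_crick")
  expect_error(classify_decoding("AG", "ACU"), "3-mers")
  expect_error(classify_decoding("AGX", "ACU"), "3-mers")
})

test_that("filters only ever shrink the numerator", {
  spec <- simulation_spec(seed = 3, n_genes = 60L,
                          per_codon_rates = c(ACT = 0.05, ACC = 0.05,
                                              ACA = 0.05, ACG = 0.05),
                          detection_prob = 0.7)
  db <- generate_proteome(spec)
  sim <- generate_psms(spec, db)
  up <- collapse_to_unique(filter_fdr(compute_qvalues(sim$psms)))
  n_raw <- sum(up$is_substituted)
  n_sib <- nrow(sibling_filter(up))
  n_loc <- nrow(unique_localization_filter(sibling_filter(up), db))
  expect_lte(n_sib, n_raw)
  expect_lte(n_loc, n_sib)
  freq_all <- mistranslation_frequency(up, spec$substitution,
                                       sibling_rule = FALSE)$frequency_pct
  freq_sib <- mistranslation_frequency(up, spec$substitution,
                                       sibling_rule = TRUE)$frequency_pct
  expect_lte(freq_sib, freq_all)
})

test_that("frequency estimates track generator truth across replicates", {
  # one proteome, many PSM-table replicates; the oracle is the expected
  # frequency computed from the generator's parameters on this digest
  base <- simulation_spec(seed = 101, n_genes = 600L,
                          per_codon_rates = c(ACT = 0.005, ACC = 0.005,
                                              ACA = 0.005, ACG = 0.005))
  db <- generate_proteome(base)
  peps <- unlist(lapply(db, function(g) {
    d <- digest_lysC(g$protein, 0L)
    d$peptide[nchar(d$peptide) >= base$min_len &
                nchar(d$peptide) <= base$max_len]
  }), use.names = FALSE)
  has_origin <- grepl("T", peps, fixed = TRUE)
  n_sites <- sum(lengths(gregexpr("T", peps[has_origin], fixed = TRUE)))
  d <- base$detection_prob; r <- 0.005
  exp_num <- d * n_sites * r            # substituted forms with sibling
  exp_den <- d * sum(has_origin) + n_sites * r
  p_exp <- 100 * exp_num / exp_den
  errs <- vapply(1:20, function(i) {
    sp <- base; sp$seed <- 200L + i
    sim <- generate_psms(sp, db)
    up <- collapse_to_unique(filter_fdr(compute_qvalues(sim$psms)))
    mistranslation_frequency(up, base$substitution)$frequency_pct - p_exp
  }, 0)
  se <- 100 * sqrt((p_exp / 100) * (1 - p_exp / 100) / (d * sum(has_origin)))
  expect_lte(mean(abs(errs)), 2 * se)
})

test_that("replicate group comparison wraps Welch t with Holm", {
  same <- compare_replicate_frequencies(c(1, 1.1, 0.9), c(1, 1.1, 0.9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$p_value, same$p_adjusted)  # m = 1: adjusted == raw
  strong <- compare_replicate_frequencies(c(1.0, 1.1, 0.9, 1.0, 1.0),
                                          rep(0, 5))
  expect_lt(strong$p_value, 0.001)
  expect_error(compare_replicate_frequencies(1, c(1, 2)), "2 replicates")
})
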