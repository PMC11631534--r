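Package: mistraq
Title: Quantifying Amino-Acid Misincorporation from Shotgun Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tRNA-induced amino-acid misincorporation
    (e.g. serine substituted at valine or threonine codons) from
    peptide-spectrum match (PSM) tables produced by a database search with
    substitution mass shifts as variable modifications. Provides monoisotopic
    mass bookkeeping for residues, substitutions and modifications; a paired
    protein/CDS sequence database with in-silico Lys-C digestion and
    peptide-to-codon localization; a transparent target-decoy q-value
    estimator with FDR filtering; residue- and codon-level misincorporation
    frequencies under the sibling-peptide and unique-localization rules;
    anticodon-codon decoding classification (Watson-Crick, inosine-34
    wobble, 3' mismatch); codon-usage accounting and gene ranking; the
    phenotype statistics battery used in mistranslation studies
    (Fisher exact, Wilcoxon rank-sum, Welch t, Holm-Bonferroni,
    Kaplan-Meier with log-rank tests, Wilson proportion intervals); and
    synthetic-data generators with ground-truth ledgers so that every
    pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    survival,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
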