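# Monoisotopic mass bookkeeping for residues, substitutions and search
# modifications. All masses are neutral residue masses in Da; peptide
# neutral mass = sum(residue masses) + water.

#' Monoisotopic residue mass table
#'
#' Masses of the 20 canonical amino-acid residues (the amino acid minus
#' water) and the mass of water, as used to define substitution mass
#' deltas and theoretical peptide masses.
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   residue masses, Da) and `water` (numeric, Da).
#' @examples
#' residue_mass_table()$residues[["G"]]
#' @export
residue_mass_table <- function() {
  list(residues = .RESIDUE_MASS, water = .WATER_MASS)
}

# Standard monoisotopic residue masses (Da). I and L are distinct residues
# with identical mass; collision scans treat I<->L pairs as unresolvable.
.RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MASS <- 18.010565

# Built-in variable/fixed modification registry (monoisotopic deltas from
# elemental composition).
.MODIFICATION_MASS <- c(
  carbamidomethyl = 57.021464,  # C2H3NO, fixed on Cys in the search design
  oxidation       = 15.994915,  # O, variable on Met
  acetyl          = 42.010565,  # C2H2O, protein N-terminal Lys
  methyl          = 14.015650,  # CH2
  trimethyl       = 42.046950,  # C3H6, near-isobar of acetyl
  phospho         = 79.966331,  # HPO3
  deamidation     =  0.984016   # -NH +OH
)

.check_residue <- function(aa, arg = "residue") {
  if (!(is.character(aa) && length(aa) == 1L && aa %in% names(.RESIDUE_MASS)))
    stop("unknown ", arg, " code: ", deparse(aa), call. = FALSE)
  invisible(aa)
}

#' Mass delta of an amino-acid substitution
#'
#' The monoisotopic mass shift incurred when `to_aa` is incorporated in
#' place of `from_aa`, i.e. `mass(to_aa) - mass(from_aa)`. This is the
#' variable-modification delta used to search for misincorporation events
#' (e.g. V->S is -12.0364 Da, T->S is -14.0156 Da).
#'
#' @param from_aa,to_aa One-letter codes of the genetically encoded and the
#'   misincorporated residue. Must differ.
#' @return Mass delta in Da (may be negative).
#' @examples
#' substitution_delta("V", "S")
#' substitution_delta("T", "S")
#' @export
substitution_delta <- function(from_aa, to_aa) {
  .check_residue(from_aa, "from_aa")
  .check_residue(to_aa, "to_aa")
  if (from_aa == to_aa)
    stop("identity substitution ", from_aa, "->", to_aa, " is not allowed",
         call. = FALSE)
  unname(.RESIDUE_MASS[[to_aa]] - .RESIDUE_MASS[[from_aa]])
}

#' Construct a substitution specification
#'
#' Bundles an origin residue, destination residue, their mass delta and a
#' display label. The delta is always recomputed from the residue mass
#' table, never taken on trust.
#'
#' @inheritParams substitution_delta
#' @param label Optional display label; defaults to `"X->Y"`.
#' @return A list of class `substitution_spec` with fields `from_aa`,
#'   `to_aa`, `delta`, `label`.
#' @export
substitution_spec <- function(from_aa, to_aa, label = NULL) {
  delta <- substitution_delta(from_aa, to_aa)
  structure(
    list(from_aa = from_aa, to_aa = to_aa, delta = delta,
         label = if (is.null(label)) paste0(from_aa, "->", to_aa) else label),
    class = "substitution_spec"
  )
}

#' @export
print.substitution_spec <- function(x, ...) {
  cat(sprintf("substitution %s (delta %+0.4f Da)\n", x$label, x$delta))
  invisible(x)
}

#' Monoisotopic delta of a named modification
#'
#' @param name Modification name; one of
#'   `names(mistraq:::.MODIFICATION_MASS)` (carbamidomethyl, oxidation,
#'   acetyl, ...).
#' @return Delta in Da.
#' @examples
#' modification_mass("carbamidomethyl")
#' @export
modification_mass <- function(name) {
  if (!(is.character(name) && length(name) == 1L &&
        name %in% names(.MODIFICATION_MASS)))
    stop("unknown modification: ", deparse(name), call. = FALSE)
  unname(.MODIFICATION_MASS[[name]])
}

#' Neutral monoisotopic mass of a peptide
#'
#' @param sequence Peptide sequence (canonical one-letter codes).
#' @param mods Optional modification list: a two-column data.frame or list
#'   with elements `position` (1-based residue index) and `delta` (Da).
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  if (!(is.character(sequence) && length(sequence) == 1L && nzchar(sequence)))
    stop("sequence must be a non-empty string", call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  m <- sum(.RESIDUE_MASS[aa]) + .WATER_MASS
  if (!is.null(mods) && length(mods$position)) {
    pos <- as.integer(mods$position)
    if (any(pos < 1L | pos > length(aa)))
      stop("modification position out of range", call. = FALSE)
    m <- m + sum(as.numeric(mods$delta))
  }
  m
}

#' Precursor mass agreement in parts per million
#'
#' `TRUE` when `|observed - theoretical| / theoretical * 1e6 <= tol_ppm`,
#' the acceptance rule for a precursor mass tolerance (20 ppm in the
#' search design this package mirrors).
#'
#' @param observed,theoretical Neutral masses in Da; `theoretical` must be
#'   positive.
#' @param tol_ppm Tolerance in ppm.
#' @return Logical vector.
#' @export
within_ppm <- function(observed, theoretical, tol_ppm = 20) {
  if (any(theoretical <= 0))
    stop("theoretical mass must be positive", call. = FALSE)
  abs(observed - theoretical) / theoretical * 1e6 <= tol_ppm
}

#' Registry of substitution and modification mass deltas
#'
#' All 380 ordered residue pairs plus the built-in modification registry,
#' used to flag near-isobaric confusions in a search design.
#'
#' @return A data.frame with columns `label`, `type`
#'   (`"substitution"`/`"modification"`), `from`, `to` (NA for
#'   modifications) and `delta_da`.
#' @export
delta_registry <- function() {
  res <- names(.RESIDUE_MASS)
  pairs <- expand.grid(from = res, to = res, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  subs <- data.frame(
    label = paste0(pairs$from, "->", pairs$to),
    type = "substitution",
    from = pairs$from, to = pairs$to,
    delta_da = unname(.RESIDUE_MASS[pairs$to] - .RESIDUE_MASS[pairs$from]),
    stringsAsFactors = FALSE
  )
  mods <- data.frame(
    label = names(.MODIFICATION_MASS),
    type = "modification",
    from = NA_character_, to = NA_character_,
    delta_da = unname(.MODIFICATION_MASS),
    stringsAsFactors = FALSE
  )
  out <- rbind(subs, mods)
  rownames(out) <- NULL
  out
}

#' Scan for near-isobaric confusions of a substitution
#'
#' Returns every registry entry whose mass delta lies within `tol` Da of
#' the query substitution's delta (the query itself excluded). Entries
#' involving only an I/L swap relative to the query are mass-identical
#' and therefore always unresolvable by precursor mass.
#'
#' @param spec A [substitution_spec()].
#' @param registry A registry data.frame as from [delta_registry()].
#' @param tol Absolute tolerance in Da (>= 0).
#' @return Subset of `registry` with an extra column `diff_da`
#'   (= delta - query delta), ordered by `abs(diff_da)` then label.
#' @export
collision_scan <- function(spec, registry = delta_registry(), tol = 0.0005) {
  stopifnot(inherits(spec, "substitution_spec"))
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0)
    stop("tol must be a single nonnegative number", call. = FALSE)
  self <- registry$type == "substitution" &
    !is.na(registry$from) & registry$from == spec$from_aa &
    !is.na(registry$to) & registry$to == spec$to_aa
  hit <- abs(registry$delta_da - spec$delta) <= tol & !self
  out <- registry[hit, , drop = FALSE]
  out$diff_da <- out$delta_da - spec$delta
  out <- out[order(abs(out$diff_da), out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the delta registry as TSV
#'
#' Writes columns `from`, `to`, `delta_da` for all substitution pairs
#' (modifications carry NA in `from`/`to`).
#'
#' @param path Output file path.
#' @param registry Registry data.frame, by default [delta_registry()].
#' @return `path`, invisibly.
#' @export
write_delta_registry <- function(path, registry = delta_registry()) {
  utils::write.table(registry[, c("from", "to", "delta_da")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
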