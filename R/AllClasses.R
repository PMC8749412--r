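#' @import methods
NULL

#' OdlPeptide: a linear peptide with resolved residue chemistry
#'
#' An `OdlPeptide` holds an ordered list of residues resolved against the
#' residue registry (each with its elemental formula and monoisotopic /
#' nominal residue mass) plus the kind of C-terminal group. The neutral
#' molecule is the residue-mass sum plus the N-terminal hydrogen and the
#' C-terminal group: a hydroxyl for a free acid, or the amide-linked
#' diaminobutane (Dbt) unit characteristic of odilorhabdins.
#'
#' Construct with [buildPeptide()] or [odlPeptide()]; do not fill slots by
#' hand.
#'
#' @slot name Display name.
#' @slot residues `data.frame` with columns `position`, `code`, `name`,
#'   `formula`, `mono`, `nominal`, `amine_sites` (comma-separated site
#'   labels; `"alpha"` is only exposed at position 1).
#' @slot cterm `"free-acid"` or `"dbt-amide"`.
#' @export
setClass("OdlPeptide",
  representation(name = "character", residues = "data.frame",
                 cterm = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@residues) < 1L)
      msg <- c(msg, "a peptide needs at least one residue")
    need <- c("position", "code", "formula", "mono", "nominal", "amine_sites")
    if (!all(need %in% names(object@residues)))
      msg <- c(msg, "residues table is missing required columns")
    else if (!identical(object@residues$position,
                        seq_len(nrow(object@residues))))
      msg <- c(msg, "residue positions must be 1..n in order")
    if (!object@cterm %in% c("free-acid", "dbt-amide"))
      msg <- c(msg, "cterm must be 'free-acid' or 'dbt-amide'")
    if (length(msg)) msg else TRUE
  })

#' AcetylConfig: a set of acetylated primary-amine sites
#'
#' Records which primary-amine sites of a peptide carry an acetyl group
#' (+42.0106 Da monoisotopic each). Sites are identified by 1-based
#' residue position, with the C-terminal Dbt amine at position n+1
#' (matching the subscript convention Lys_1 ... Dbt_11). Within-residue
#' labels (alpha vs epsilon) are tracked but are mass-degenerate.
#'
#' @slot sites `data.frame` with columns `position` (integer) and `label`
#'   (character).
#' @export
setClass("AcetylConfig",
  representation(sites = "data.frame"),
  validity = function(object) {
    s <- object@sites
    if (!all(c("position", "label") %in% names(s)))
      return("sites needs 'position' and 'label' columns")
    if (anyDuplicated(s[c("position", "label")]))
      return("duplicate (position, label) site")
    TRUE
  })

#' TheoreticalSpectrum: a computed fragment-ion ladder
#'
#' The union of precursor ions, singly charged b/y series, and the
#' secondary C-terminal neutral-loss ions for one peptide under one acetyl
#' configuration. Ions are deduplicated and sorted by m/z.
#'
#' @slot ions `data.frame` with columns `series`, `index`, `charge`, `mz`,
#'   `label`, `removed` (residue positions lost as secondary neutrals,
#'   comma string, `""` if none) and `span` (list column of residue
#'   positions covered by the ion; position n+1 denotes the Dbt group).
#' @slot peptide The parent [OdlPeptide-class].
#' @slot config The [AcetylConfig-class] applied.
#' @export
setClass("TheoreticalSpectrum",
  representation(ions = "data.frame", peptide = "OdlPeptide",
                 config = "AcetylConfig"),
  validity = function(object) {
    io <- object@ions
    need <- c("series", "index", "charge", "mz", "label", "removed")
    if (!all(need %in% names(io)))
      return("ions table is missing required columns")
    if (nrow(io) && any(io$mz <= 0)) return("ion m/z must be positive")
    if (nrow(io) && is.unsorted(io$mz)) return("ions must be sorted by m/z")
    if (anyDuplicated(io[c("series", "index", "charge", "removed")]))
      return("duplicate (series, index, charge, removed) ion")
    TRUE
  })

#' ObservedSpectrum: an experimental peak list
#'
#' A peak list as read from an MGF file, a two-column CSV, or built by the
#' synthetic-spectrum generator. Peaks are kept sorted by m/z. The
#' `decimals` column records how many decimal places each m/z was printed
#' with (NA when constructed from full-precision numbers); tolerance-based
#' matching widens the window for coarsely printed peaks.
#'
#' @slot peaks `data.frame` with columns `mz`, `intensity`, `decimals`.
#' @slot precursorMz Precursor m/z (NA if unknown).
#' @slot precursorCharge Precursor charge (NA if unknown).
#' @export
setClass("ObservedSpectrum",
  representation(peaks = "data.frame", precursorMz = "numeric",
                 precursorCharge = "integer"),
  validity = function(object) {
    pk <- object@peaks
    if (!all(c("mz", "intensity", "decimals") %in% names(pk)))
      return("peaks needs 'mz', 'intensity', 'decimals' columns")
    if (nrow(pk) && any(pk$mz <= 0)) return("peak m/z must be positive")
    if (nrow(pk) && is.unsorted(pk$mz)) return("peaks must be sorted by m/z")
    TRUE
  })
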