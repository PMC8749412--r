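#' @include residues.R AllGenerics.R
NULL

## C-terminal group chemistry. The neutral molecule is
##   sum(residue masses) + N-terminal H + C-terminal group,
## where the group is OH for a free acid, or the amide-linked
## diaminobutane unit (diamine minus one H) for the Dbt terminus. The
## Dbt group departs in MS/MS as the free neutral diamine C4H12N2.
.ctermSpec <- function(kind) {
  switch(kind,
    "free-acid" = list(
      mono = .MONO[["O"]] + .MONO[["H"]], nominal = 17L,
      loss_mono = NA_real_, loss_nominal = NA_integer_,
      amine = FALSE, code = ""),
    "dbt-amide" = list(
      mono = formulaMass("C4H11N2"), nominal = 87L,
      loss_mono = formulaMass("C4H12N2"),    # 88.1001 Da free diamine
      loss_nominal = 88L,
      amine = TRUE, code = "Dbt"),
    stop("unknown C-terminal group kind: '", kind, "'"))
}

.NTERM_H <- function(mode) if (mode == "monoisotopic") .MONO[["H"]] else 1L

#' Build a peptide from residue tokens
#'
#' Resolves an ordered vector of residue codes against the active residue
#' registry and attaches a C-terminal group.
#'
#' @param tokens Character vector of registered residue codes, N- to
#'   C-terminal.
#' @param cterm `"free-acid"` (default) or `"dbt-amide"` for the
#'   odilorhabdin diaminobutane secondary amide.
#' @param name Display name.
#' @return An [OdlPeptide-class].
#' @examples
#' buildPeptide(c("Gly", "Gly"))
#' @export
buildPeptide <- function(tokens, cterm = c("free-acid", "dbt-amide"),
                         name = paste(tokens, collapse = "-")) {
  cterm <- match.arg(cterm)
  if (length(tokens) < 1L) stop("empty token list")
  reg <- residueRegistry()
  i <- match(tokens, reg$code)
  if (anyNA(i))
    stop("unknown residue code: ",
         paste(sQuote(unique(tokens[is.na(i)])), collapse = ", "))
  res <- reg[i, , drop = FALSE]
  res$position <- seq_along(tokens)
  rownames(res) <- NULL
  new("OdlPeptide", name = name,
      residues = res[c("position", "code", "name", "formula", "mono",
                       "nominal", "amine_sites")],
      cterm = cterm)
}

#' Shipped odilorhabdin peptide presets
#'
#' Returns one of the named peptides shipped with the package:
#' `"NOSO-95C"` (the canonical 10-residue odilorhabdin with Dbt amide),
#' `"NOSO-95B"` and `"NOSO-95A"` (one and two hydroxylysines replacing
#' the lysines at positions 8/10), and `"NOSO-95179"` (a 9-residue
#' free-acid analog with Ala at position 3 and no Lys10-Dbt11 unit).
#'
#' @param preset Preset name; `odlPresets()` lists them.
#' @return An [OdlPeptide-class].
#' @examples
#' odlPeptide("NOSO-95C")
#' @export
odlPeptide <- function(preset) {
  tab <- odlPresets()
  i <- match(preset, tab$name)
  if (is.na(i)) stop("unknown preset '", preset, "'; see odlPresets()")
  buildPeptide(strsplit(tab$tokens[i], " ", fixed = TRUE)[[1]],
               cterm = tab$cterm[i], name = tab$name[i])
}

#' @rdname odlPeptide
#' @export
odlPresets <- function() {
  utils::read.delim(system.file("extdata", "peptides.tsv",
                                package = "odltools", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Enumerate primary-amine acetylation sites
#'
#' Lists every primary amine available for N-acetylation: the backbone
#' alpha amine of position 1 (when the residue has one), each side-chain
#' amine declared in the residue table, and the terminal amine of the Dbt
#' group (position n+1). For NOSO-95C this census yields 8 sites.
#'
#' @param p An [OdlPeptide-class].
#' @return `data.frame` with columns `position`, `label`, `code`, ordered
#'   by position (alpha before side-chain within a residue).
#' @examples
#' enumerateAmineSites(odlPeptide("NOSO-95C"))
#' @export
enumerateAmineSites <- function(p) {
  stopifnot(is(p, "OdlPeptide"))
  res <- residues(p)
  out <- list()
  for (i in seq_len(nrow(res))) {
    labs <- .residueAmineLabels(res[i, ])
    if (i > 1L) labs <- setdiff(labs, "alpha")  # backbone amide upstream
    if (length(labs))
      out[[length(out) + 1L]] <- data.frame(
        position = res$position[i], label = labs, code = res$code[i],
        stringsAsFactors = FALSE)
  }
  ct <- .ctermSpec(cterm(p))
  if (ct$amine)
    out[[length(out) + 1L]] <- data.frame(
      position = nrow(res) + 1L, label = "terminal", code = "Dbt",
      stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(position = integer(), label = character(),
                      code = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Define an acetyl configuration
#'
#' Builds an [AcetylConfig-class] for `k` acetyl groups placed on the
#' peptide's primary-amine sites. Sites are addressed by residue position
#' (the Dbt terminus is position n+1). When a position offers several
#' amines (Lys1 alpha vs epsilon) and no label is given, the first
#' declared label is taken: the choice is mass-degenerate and fragment
#' spectra cannot distinguish it.
#'
#' @param p An [OdlPeptide-class].
#' @param positions Integer vector of acetylated residue positions
#'   (empty for the native compound).
#' @param labels Optional character vector of site labels, parallel to
#'   `positions`.
#' @return An [AcetylConfig-class].
#' @examples
#' p <- odlPeptide("NOSO-95C")
#' acetylConfig(p, c(2, 3, 10))   # the triacetylated form
#' @export
acetylConfig <- function(p, positions = integer(), labels = NULL) {
  sites <- enumerateAmineSites(p)
  positions <- as.integer(positions)
  if (!is.null(labels) && length(labels) != length(positions))
    stop("'labels' must be parallel to 'positions'")
  pick <- lapply(seq_along(positions), function(j) {
    cand <- sites[sites$position == positions[j], , drop = FALSE]
    if (!nrow(cand))
      stop("no primary-amine site at position ", positions[j],
           " of ", peptideName(p))
    if (!is.null(labels)) {
      cand <- cand[cand$label == labels[j], , drop = FALSE]
      if (!nrow(cand))
        stop("no site labelled '", labels[j], "' at position ", positions[j])
    }
    cand[1L, c("position", "label")]
  })
  sites_df <- if (length(pick)) do.call(rbind, pick) else
    data.frame(position = integer(), label = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(sites_df))
    stop("duplicate acetyl site requested")
  rownames(sites_df) <- NULL
  new("AcetylConfig", sites = sites_df)
}

#' Neutral mass of a (possibly acetylated) peptide
#'
#' Sum of residue masses plus the N-terminal hydrogen and C-terminal
#' group, plus one acetyl mass (monoisotopic 42.0106 Da, nominal 42 Da)
#' per configured site.
#'
#' @param p An [OdlPeptide-class].
#' @param config An [AcetylConfig-class]; default none.
#' @param mode `"monoisotopic"` (default) or `"nominal"`.
#' @return Neutral mass in Da.
#' @examples
#' neutralMass(odlPeptide("NOSO-95C"))  # 1263.80 Da, prints as MW 1264
#' @export
neutralMass <- function(p, config = acetylConfig(p),
                        mode = c("monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  stopifnot(is(p, "OdlPeptide"), is(config, "AcetylConfig"))
  .checkConfig(p, config)
  res <- residues(p)
  ct <- .ctermSpec(cterm(p))
  k <- nrow(acetylSites(config))
  if (mode == "monoisotopic")
    sum(res$mono) + .MONO[["H"]] + ct$mono + k * .ACETYL_MONO
  else
    sum(res$nominal) + 1L + ct$nominal + k * .ACETYL_NOMINAL
}

.checkConfig <- function(p, config) {
  sites <- enumerateAmineSites(p)
  s <- acetylSites(config)
  ok <- paste(s$position, s$label) %in% paste(sites$position, sites$label)
  if (!all(ok))
    stop("acetyl site not present on peptide: ",
         paste(paste0(s$position[!ok], "(", s$label[!ok], ")"),
               collapse = ", "))
  invisible(TRUE)
}

#' Precursor m/z
#'
#' `[M + zH]z+` m/z of the (possibly acetylated) neutral molecule, with a
#' proton mass of 1.00728 Da.
#'
#' @inheritParams neutralMass
#' @param charge Positive integer charge state.
#' @return m/z in Th.
#' @examples
#' precursorMzOf(odlPeptide("NOSO-95C"), charge = 2)  # prints as 633
#' @export
precursorMzOf <- function(p, config = acetylConfig(p), charge = 1L,
                          mode = c("monoisotopic", "nominal")) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  (neutralMass(p, config, mode) + charge * .PROTON) / charge
}
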