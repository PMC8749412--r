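#' @include peptide.R
NULL

## Fragment-ion calculus.
##
## The C-terminal Dbt group is counted as one ladder unit, matching the
## subscript convention in which a 10-residue odilorhabdin runs Lys_1 ..
## Dbt_11 and its largest y ion is y_10. All chain fragments are singly
## charged; only the precursor is emitted at higher charge states.

.acetylShift <- function(span, configPositions) {
  .ACETYL_MONO * sum(configPositions %in% span)
}

.ionRow <- function(series, index, charge, mz, label, removed, span) {
  data.frame(series = series, index = index, charge = charge, mz = mz,
             label = label, removed = removed, span = I(list(span)),
             stringsAsFactors = FALSE)
}

#' Singly charged y-series
#'
#' y_k covers the C-terminal k ladder units (the Dbt group counting as
#' one unit when present): the residue-mass sum plus the C-terminal
#' group, an N-terminal hydrogen and a proton, shifted by +42.0106 Da for
#' each acetylated site inside the span.
#'
#' @param p An [OdlPeptide-class].
#' @param config An [AcetylConfig-class].
#' @return `data.frame` of ions (columns as in
#'   [TheoreticalSpectrum-class]).
#' @examples
#' ySeries(odlPeptide("NOSO-95C"))  # y10 = 1136.7 for the native compound
#' @export
ySeries <- function(p, config = acetylConfig(p)) {
  .checkConfig(p, config)
  res <- residues(p)
  n <- nrow(res)
  ct <- .ctermSpec(cterm(p))
  dbt <- cterm(p) == "dbt-amide"
  nu <- n + dbt                       # ladder units
  cpos <- acetylSites(config)$position
  rows <- lapply(seq_len(nu - 1L), function(k) {
    first <- n - k + 1L + dbt         # first chain position in span
    span <- if (first <= n) first:n else integer()
    if (dbt) span <- c(span, n + 1L)
    mz <- sum(res$mono[span[span <= n]]) + .MONO[["H"]] + ct$mono +
      .PROTON + .acetylShift(span, cpos)
    .ionRow("y", k, 1L, mz, paste0("y", k), "", span)
  })
  do.call(rbind, rows)
}

#' Singly charged b-series
#'
#' b_i covers the N-terminal i residues: the residue-mass sum plus a
#' proton, shifted for acetylated sites in the span. The C-terminal group
#' never enters a b ion.
#'
#' @inheritParams ySeries
#' @return `data.frame` of ions.
#' @export
bSeries <- function(p, config = acetylConfig(p)) {
  .checkConfig(p, config)
  res <- residues(p)
  n <- nrow(res)
  if (n < 2L)
    return(.ionRow("b", 1L, 1L, 1, "b1", "", 1L)[0, ])
  cpos <- acetylSites(config)$position
  rows <- lapply(seq_len(n - 1L), function(i) {
    span <- seq_len(i)
    mz <- sum(res$mono[span]) + .PROTON + .acetylShift(span, cpos)
    .ionRow("b", i, 1L, mz, paste0("b", i), "", span)
  })
  do.call(rbind, rows)
}

#' Secondary C-terminal losses from a y ion
#'
#' Odilorhabdin y ions (and the protonated molecule) lose the Dbt group
#' as a free neutral diamine (88.10 Da; 130.11 Da if the terminal amine
#' is acetylated) and can then shed further C-terminal residues. The loss
#' of depth d removes the Dbt unit plus the last d-1 chain residues of
#' the ion, each leaving with its own acetyl when modified.
#'
#' @param ion A single-row ion `data.frame` as produced by [ySeries()]
#'   (must span the C-terminus of a Dbt-amide peptide).
#' @param p,config Parent peptide and acetyl configuration.
#' @param maxDepth Deepest suffix removed, the Dbt group counting as
#'   depth 1. Default 2 (the deepest loss used in practice is
#'   Lys10-Dbt11).
#' @return `data.frame` of secondary-loss ions (possibly empty).
#' @export
secondaryLosses <- function(ion, p, config = acetylConfig(p), maxDepth = 2L) {
  .checkConfig(p, config)
  res <- residues(p)
  n <- nrow(res)
  if (cterm(p) != "dbt-amide") return(.ionRow("y", 1, 1, 1, "", "", 1)[0, ])
  span <- ion$span[[1]]
  if (!(n + 1L) %in% span)
    stop("secondary losses require an ion spanning the C-terminal Dbt group")
  ct <- .ctermSpec(cterm(p))
  cpos <- acetylSites(config)$position
  unitName <- function(q) {
    code <- if (q > n) "Dbt" else res$code[q]
    paste0(if (q %in% cpos) "Ac" else "", code, q)
  }
  rows <- list()
  mz <- ion$mz
  removed <- integer()
  for (d in seq_len(maxDepth)) {
    chainLeft <- setdiff(intersect(span, seq_len(n)), removed)
    ## never strip the ion bare: keep at least one chain residue
    if (length(chainLeft) <= (d > 1L)) break
    lose <- if (d == 1L) n + 1L else max(chainLeft)
    loss <- if (lose == n + 1L) ct$loss_mono else res$mono[lose]
    if (lose %in% cpos) loss <- loss + .ACETYL_MONO
    mz <- mz - loss
    removed <- c(removed, lose)
    lab <- paste0(ion$label, " - ",
                  paste(vapply(sort(removed), unitName, character(1)),
                        collapse = "-"))
    rows[[d]] <- .ionRow("secondary-loss", ion$index, 1L, mz, lab,
                         paste(sort(removed), collapse = ","),
                         setdiff(span, removed))
  }
  if (!length(rows)) return(.ionRow("y", 1, 1, 1, "", "", 1)[0, ])
  do.call(rbind, rows)
}

#' Full theoretical spectrum
#'
#' Union of the precursor at each requested charge, the singly charged
#' b/y series, and the secondary C-terminal losses from every y ion,
#' deduplicated on (series, index, charge, removed) and sorted by m/z.
#'
#' @inheritParams ySeries
#' @param charges Integer vector of precursor charge states.
#' @param maxDepth Secondary-loss depth (see [secondaryLosses()]).
#' @return A [TheoreticalSpectrum-class].
#' @examples
#' theoreticalSpectrum(odlPeptide("NOSO-95C"))
#' @export
theoreticalSpectrum <- function(p, config = acetylConfig(p),
                                charges = c(1L, 2L), maxDepth = 2L) {
  if (!length(charges)) stop("'charges' must be nonempty")
  prec <- do.call(rbind, lapply(as.integer(charges), function(z) {
    .ionRow("precursor", 0L, z, precursorMzOf(p, config, z),
            if (z == 1L) "[M+H]+" else sprintf("[M+%dH]%d+", z, z),
            "", c(seq_len(nResidues(p)),
                  if (cterm(p) == "dbt-amide") nResidues(p) + 1L))
  }))
  ys <- ySeries(p, config)
  bs <- bSeries(p, config)
  sec <- if (cterm(p) == "dbt-amide" && maxDepth >= 1L)
    do.call(rbind, lapply(seq_len(nrow(ys)), function(i)
      secondaryLosses(ys[i, ], p, config, maxDepth)))
  else NULL
  io <- rbind(prec, ys, bs, sec)
  io <- io[!duplicated(io[c("series", "index", "charge", "removed")]), ]
  io <- io[io$mz > 0, ]
  io <- io[order(io$mz), ]
  rownames(io) <- NULL
  new("TheoreticalSpectrum", ions = io, peptide = p, config = config)
}
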