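#' @include localize.R
NULL

.unitNominal <- function(p, q) {
  res <- residues(p)
  n <- nrow(res)
  if (q > n) .ctermSpec(cterm(p))$loss_nominal else res$nominal[q]
}

.unitName <- function(p, q, cpos) {
  res <- residues(p)
  n <- nrow(res)
  code <- if (q > n) "Dbt" else res$code[q]
  paste0(if (q %in% cpos) "Ac" else "", code, q)
}

.lossLabel <- function(p, units, cpos) {
  if (!length(units)) return("")
  masses <- vapply(units, function(q)
    .unitNominal(p, q) + if (q %in% cpos) 42L else 0L, numeric(1))
  if (length(masses) == 1L) as.character(masses)
  else sprintf("%d (%s)", sum(masses), paste(masses, collapse = " + "))
}

.structureString <- function(p, span, cpos) {
  res <- residues(p)
  n <- nrow(res)
  span <- sort(span)
  paste(vapply(span, function(q) {
    code <- if (q > n) "Dbt" else res$code[q]
    paste0(if (q %in% cpos) "Ac" else "", code)
  }, character(1)), collapse = "-")
}

#' Annotate an observed spectrum against one acetyl configuration
#'
#' Produces the four-column annotation layout used for odilorhabdin
#' MS/MS tables: ion label, observed m/z, nominal neutral loss from the
#' previous ion in the ladder, the residue(s) lost, and the assigned
#' remaining structure with "Ac" prefixes on acetylated residues. Rows
#' run down the y ladder with secondary C-terminal losses nested under
#' their parent y ion; b ions close the table. Observed peaks that match
#' no theoretical ion are appended as an `unassigned` trailer.
#'
#' Neutral-loss labels use nominal residue masses (e.g. a Lys unit prints
#' 128, an AcDab(bOH) unit 158, the Lys-Dbt pair "216 (128 + 88)");
#' matching itself is always done on monoisotopic m/z.
#'
#' @inheritParams localizeAcetyl
#' @param config The [AcetylConfig-class] to annotate under.
#' @return `data.frame` with columns `ion`, `mz`, `neutral_loss`,
#'   `attribution`, `assigned_structure`.
#' @examples
#' p <- odlPeptide("NOSO-95C")
#' obs <- readPeakList(odlFixture("table2_tri.mgf"))
#' annotateSpectrum(obs, p, acetylConfig(p, c(2, 3, 10)))
#' @export
annotateSpectrum <- function(obs, p, config, tol = 0.5,
                             charges = c(1L, 2L), maxDepth = 2L) {
  theo <- theoreticalSpectrum(p, config, charges, maxDepth)
  m <- matchPeaks(obs, theo, tol)
  io <- ions(theo)
  cpos <- acetylSites(config)$position
  n <- nResidues(p)
  nu <- n + (cterm(p) == "dbt-amide")
  obsOf <- function(j) m$mz_obs[match(j, m$ion)]
  rows <- list()
  addRow <- function(ion, mz, loss, attr, span) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ion = ion, mz = mz, neutral_loss = loss, attribution = attr,
      assigned_structure = .structureString(p, span, cpos),
      stringsAsFactors = FALSE)
  }
  ## precursors, highest charge first (Table style lists [M+2H]2+)
  ip <- which(io$series == "precursor" & !is.na(obsOf(seq_len(nrow(io)))) &
              seq_len(nrow(io)) %in% m$ion)
  for (j in ip[order(-io$charge[ip])])
    addRow(io$label[j], obsOf(j), "", "", io$span[[j]])
  ## y ladder, descending, with nested secondary losses
  yIdx <- io$index[io$series == "y" & seq_len(nrow(io)) %in% m$ion]
  for (k in sort(unique(yIdx), decreasing = TRUE)) {
    j <- which(io$series == "y" & io$index == k)
    spanY <- io$span[[j]]
    ## units lost relative to the previous listed y ion (or the molecule)
    larger <- yIdx[yIdx > k]
    prevSpan <- if (length(larger))
      io$span[[which(io$series == "y" & io$index == min(larger))]]
    else c(seq_len(n), if (nu > n) n + 1L)
    lost <- setdiff(prevSpan, spanY)
    addRow(io$label[j], obsOf(j), .lossLabel(p, sort(lost), cpos),
           paste(vapply(sort(lost), .unitName, character(1), p = p,
                        cpos = cpos), collapse = "-"),
           spanY)
    ## nested losses, shallow to deep, each relative to the previous row
    ch <- which(io$series == "secondary-loss" & io$index == k &
                seq_len(nrow(io)) %in% m$ion)
    ch <- ch[order(nchar(io$removed[ch]))]
    prev <- spanY
    for (jj in ch) {
      lost <- setdiff(prev, io$span[[jj]])
      addRow("", obsOf(jj), .lossLabel(p, sort(lost), cpos),
             paste(vapply(sort(lost), .unitName, character(1), p = p,
                          cpos = cpos), collapse = "-"),
             io$span[[jj]])
      prev <- io$span[[jj]]
    }
  }
  ## b ions, descending, losses expressed against the whole molecule
  ib <- which(io$series == "b" & seq_len(nrow(io)) %in% m$ion)
  for (j in ib[order(-io$index[ib])]) {
    lost <- setdiff(c(seq_len(n), if (nu > n) n + 1L), io$span[[j]])
    addRow(io$label[j], obsOf(j), .lossLabel(p, sort(lost), cpos),
           paste(vapply(sort(lost), .unitName, character(1), p = p,
                        cpos = cpos), collapse = "-"),
           io$span[[j]])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ion = character(), mz = numeric(),
               neutral_loss = character(), attribution = character(),
               assigned_structure = character(), stringsAsFactors = FALSE)
  ## unassigned trailer
  un <- setdiff(seq_len(nrow(peaks(obs))), m$peak)
  if (length(un))
    out <- rbind(out, data.frame(
      ion = "unassigned", mz = peaks(obs)$mz[un], neutral_loss = "",
      attribution = "", assigned_structure = "", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Species fractions and peak-area ratios
#'
#' Book-keeping for acetylation time courses: converts per-species peak
#' areas (native / mono / bi / tri) into fractions of the total and the
#' requested pairwise area ratios, e.g. biacetylated/triacetylated.
#'
#' @param areas Named non-negative numeric vector of peak areas.
#' @param ratios Optional character matrix-like list of pairs
#'   `c(numerator, denominator)`; default: all ordered pairs of detected
#'   (area > 0) species.
#' @return A list with `table` (`data.frame`: species, area, fraction)
#'   and `ratios` (`data.frame`: num, den, ratio; flagged `NA` when the
#'   denominator species was not detected).
#' @examples
#' quantifySpecies(c(bi = 100, tri = 4))$ratios  # bi/tri = 25
#' @export
quantifySpecies <- function(areas, ratios = NULL) {
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("'areas' must be a named vector")
  if (any(areas < 0)) stop("peak areas must be non-negative")
  if (all(areas == 0)) stop("all peak areas are zero")
  tab <- data.frame(species = names(areas), area = as.numeric(areas),
                    fraction = as.numeric(areas) / sum(areas),
                    stringsAsFactors = FALSE)
  if (is.null(ratios)) {
    det <- tab$species[tab$area > 0]
    ratios <- if (length(det) >= 2L)
      utils::combn(det, 2L, simplify = FALSE) else list()
  }
  rt <- if (length(ratios)) do.call(rbind, lapply(ratios, function(pr) {
    a <- tab$area[match(pr[1], tab$species)]
    b <- tab$area[match(pr[2], tab$species)]
    data.frame(num = pr[1], den = pr[2],
               ratio = if (!is.na(b) && b > 0) a / b else NA_real_,
               stringsAsFactors = FALSE)
  })) else data.frame(num = character(), den = character(),
                      ratio = numeric(), stringsAsFactors = FALSE)
  list(table = tab, ratios = rt)
}
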