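#' @include fragments.R
NULL

## Per-peak matching tolerance. Peaks printed without decimals (Table-2
## style integer m/z) get a full-unit window; one-decimal and
## full-precision peaks use the user tolerance (default 0.5 Da,
## quadrupole scale).
.peakTolerance <- function(decimals, tol) {
  widen <- !is.na(decimals) & decimals == 0L
  ifelse(widen, pmax(tol, 1.0), tol)
}

#' Construct an observed spectrum
#'
#' @param mz Numeric peak m/z values.
#' @param intensity Peak intensities (default unit).
#' @param precursorMz,precursorCharge Precursor information (NA if
#'   unknown).
#' @param decimals Integer vector: printed decimal places per peak (NA =
#'   full precision). Used to widen the matching tolerance for coarsely
#'   printed peaks.
#' @return An [ObservedSpectrum-class].
#' @export
observedSpectrum <- function(mz, intensity = rep(1, length(mz)),
                             precursorMz = NA_real_,
                             precursorCharge = NA_integer_,
                             decimals = rep(NA_integer_, length(mz))) {
  o <- order(mz)
  new("ObservedSpectrum",
      peaks = data.frame(mz = mz[o], intensity = intensity[o],
                         decimals = as.integer(decimals)[o]),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge))
}

#' Infer the acetyl count from the precursor shift
#'
#' Each acetyl adds 42.0106 Da to the neutral molecule; the count is the
#' rounded precursor-derived neutral-mass excess over the unmodified
#' peptide divided by the acetyl mass. A residual off the acetyl lattice
#' larger than `tol` is an error (the spectrum is not an acetyl series of
#' this peptide).
#'
#' @param obs An [ObservedSpectrum-class] with precursor m/z and charge.
#' @param p An [OdlPeptide-class].
#' @param tol Residual tolerance in Da (default 1.0, matching
#'   integer-printed precursors).
#' @return Integer k, with attribute `"residual"` (Da).
#' @examples
#' obs <- observedSpectrum(1178, precursorMz = 1307, precursorCharge = 1)
#' inferAcetylCount(obs, odlPeptide("NOSO-95C"))  # 1
#' @export
inferAcetylCount <- function(obs, p, tol = 1.0) {
  z <- precursorCharge(obs)
  mzp <- precursorMz(obs)
  if (is.na(z) || is.na(mzp))
    stop("observed spectrum has no precursor m/z / charge")
  neutral <- z * mzp - z * .PROTON
  base <- neutralMass(p)
  k <- round((neutral - base) / .ACETYL_MONO)
  residual <- neutral - (base + k * .ACETYL_MONO)
  if (k < 0)
    stop("observed precursor is lighter than the unmodified peptide")
  nsites <- nrow(enumerateAmineSites(p))
  if (k > nsites)
    stop("inferred acetyl count ", k, " exceeds the ", nsites,
         " primary-amine sites")
  if (abs(residual) > tol)
    stop(sprintf(paste0("precursor residual %.2f Da off the acetyl",
                        " lattice (not an acetyl series of %s)"),
                 residual, peptideName(p)))
  structure(as.integer(k), residual = residual)
}

#' Match observed peaks to a theoretical ladder
#'
#' Greedy nearest-first matching: candidate (peak, ion) pairs within the
#' per-peak tolerance are accepted in order of increasing absolute error,
#' each observed peak pairing with at most one theoretical ion and vice
#' versa.
#'
#' @param obs An [ObservedSpectrum-class].
#' @param theo A [TheoreticalSpectrum-class].
#' @param tol User matching tolerance in Da (default 0.5); integer-printed
#'   peaks are widened to 1.0 Da.
#' @return `data.frame` with columns `peak`, `mz_obs`, `ion`, `mz_theo`,
#'   `error`, `label` (one row per accepted pair).
#' @export
matchPeaks <- function(obs, theo, tol = 0.5) {
  pk <- peaks(obs)
  io <- ions(theo)
  empty <- data.frame(peak = integer(), mz_obs = numeric(),
                      ion = integer(), mz_theo = numeric(),
                      error = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pk) || !nrow(io)) return(empty)
  ptol <- .peakTolerance(pk$decimals, tol)
  cand <- expand.grid(peak = seq_len(nrow(pk)), ion = seq_len(nrow(io)))
  cand$error <- pk$mz[cand$peak] - io$mz[cand$ion]
  cand <- cand[abs(cand$error) <= ptol[cand$peak], , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(abs(cand$error)), , drop = FALSE]
  usedP <- logical(nrow(pk)); usedI <- logical(nrow(io))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$peak[r]; j <- cand$ion[r]
    if (!usedP[i] && !usedI[j]) {
      keep[r] <- TRUE; usedP[i] <- TRUE; usedI[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(peak = cand$peak, mz_obs = pk$mz[cand$peak],
                    ion = cand$ion, mz_theo = io$mz[cand$ion],
                    error = cand$error, label = io$label[cand$ion],
                    stringsAsFactors = FALSE)
  out[order(out$peak), ]
}

#' Residue-level candidate configurations
#'
#' All ways of placing k acetyl groups on distinct amine-bearing residue
#' positions (the Dbt terminus counting as a position). Within-residue
#' amine choices (Lys1 alpha vs epsilon) are mass-degenerate and
#' represented by a single class.
#'
#' @param p An [OdlPeptide-class].
#' @param k Number of acetyl groups.
#' @return Named list of [AcetylConfig-class] objects; names are class
#'   labels such as `"{Dab(bOH)2,Lys10}"`.
#' @export
candidateConfigs <- function(p, k) {
  sites <- enumerateAmineSites(p)
  posn <- sort(unique(sites$position))
  if (k > length(posn))
    stop("k = ", k, " exceeds the ", length(posn),
         " amine-bearing positions")
  sets <- if (k == 0L) list(integer()) else
    utils::combn(posn, k, simplify = FALSE)
  cfgs <- lapply(sets, function(s) acetylConfig(p, s))
  names(cfgs) <- vapply(sets, function(s) configLabel(p, s), character(1))
  cfgs
}

#' @rdname candidateConfigs
#' @param positions Integer vector of acetylated positions.
#' @export
configLabel <- function(p, positions) {
  if (!length(positions)) return("{}")
  res <- residues(p)
  n <- nrow(res)
  nm <- vapply(sort(positions), function(q)
    paste0(if (q > n) "Dbt" else res$code[q], q), character(1))
  paste0("{", paste(nm, collapse = ","), "}")
}

#' Localize acetyl groups on a peptide
#'
#' Scores every residue-level candidate configuration of k acetyl groups
#' against the observed peak list and ranks them by matched-peak count,
#' then by count of discriminating matches (peaks matched by this
#' configuration and no other candidate), then by summed absolute error.
#' Ties are reported jointly via the `tied` flag, never broken silently.
#'
#' @param obs An [ObservedSpectrum-class].
#' @param p An [OdlPeptide-class].
#' @param k Acetyl count; inferred from the precursor when `NULL`. When
#'   both are available and disagree, the precursor-derived count wins
#'   with a warning.
#' @param tol Matching tolerance in Da (see [matchPeaks()]).
#' @param charges Precursor charge states generated for the theoretical
#'   ladders.
#' @param maxDepth Secondary-loss depth.
#' @return `data.frame` with one row per candidate class: `class`,
#'   `n_matched`, `discriminating`, `sum_abs_error`, `rank`, `tied`,
#'   sorted best-first, plus attributes `k`, `matches` (per-class match
#'   tables) and `indeterminate` (TRUE when no peak matched anywhere).
#' @examples
#' p <- odlPeptide("NOSO-95C")
#' obs <- readPeakList(odlFixture("table2_mono.mgf"))
#' localizeAcetyl(obs, p)
#' @export
localizeAcetyl <- function(obs, p, k = NULL, tol = 0.5, charges = c(1L, 2L),
                           maxDepth = 2L) {
  kPrec <- tryCatch(inferAcetylCount(obs, p),
                    error = function(e) NULL)
  if (is.null(k)) {
    if (is.null(kPrec))
      stop("no usable precursor; supply k explicitly")
    k <- kPrec
  } else if (!is.null(kPrec) && k != kPrec) {
    warning("user k = ", k, " disagrees with precursor-derived k = ",
            kPrec, "; using the precursor-derived count")
    k <- kPrec
  }
  cfgs <- candidateConfigs(p, k)
  matches <- lapply(cfgs, function(cf)
    matchPeaks(obs, theoreticalSpectrum(p, cf, charges, maxDepth), tol))
  matchedSets <- lapply(matches, function(m) unique(m$peak))
  nm <- vapply(matches, nrow, integer(1))
  disc <- vapply(seq_along(matches), function(i) {
    others <- unique(unlist(matchedSets[-i]))
    length(setdiff(matchedSets[[i]], others))
  }, integer(1))
  sae <- vapply(matches, function(m) sum(abs(m$error)), numeric(1))
  out <- data.frame(class = names(cfgs), n_matched = nm,
                    discriminating = disc, sum_abs_error = sae,
                    stringsAsFactors = FALSE)
  o <- order(-out$n_matched, -out$discriminating, out$sum_abs_error,
             out$class)
  out <- out[o, ]
  key <- paste(out$n_matched, out$discriminating,
               signif(out$sum_abs_error, 9))
  out$rank <- match(key, unique(key))
  out$tied <- ave(seq_len(nrow(out)), out$rank, FUN = length) > 1
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "matches") <- matches[o]
  attr(out, "configs") <- cfgs[o]
  attr(out, "indeterminate") <- all(out$n_matched == 0L)
  out
}

#' Top-ranked acetyl configuration(s)
#'
#' Convenience accessor for the best class(es) of a [localizeAcetyl()]
#' result.
#'
#' @param ranking Result of [localizeAcetyl()].
#' @return Character vector of class labels sharing rank 1.
#' @export
topConfig <- function(ranking) ranking$class[ranking$rank == 1L]
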