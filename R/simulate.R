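#' @include localize.R
NULL

#' Noise parameters for the synthetic-spectrum generator
#'
#' Defaults describe a quadrupole-scale LC-MS/MS acquisition: Gaussian
#' m/z jitter of 0.05 Da (instruments reporting one decimal), one peak in
#' five lost to dropout, and ten uniform decoy peaks across the scanned
#' range.
#'
#' @param jitter_sd Gaussian m/z perturbation SD in Da (>= 0).
#' @param dropout_p Probability a true fragment ion is omitted (0..1);
#'   the precursor is always retained.
#' @param n_decoys Number of uniform random decoy peaks.
#' @param mz_range Scanned m/z window for decoys.
#' @param seed Integer seed; identical seeds give identical spectra.
#' @param exclude_near_true Keep decoys at least `tol` away from every
#'   true ion (default TRUE); when FALSE the collision count is reported
#'   in attribute `"collisions"` of the simulated spectrum.
#' @param tol Exclusion half-window in Da.
#' @return A list of class `"NoiseParams"`.
#' @export
noiseParams <- function(jitter_sd = 0.05, dropout_p = 0.2, n_decoys = 10L,
                        mz_range = c(200, 1400), seed = 1L,
                        exclude_near_true = TRUE, tol = 0.5) {
  stopifnot(jitter_sd >= 0, dropout_p >= 0, dropout_p <= 1,
            n_decoys >= 0, length(mz_range) == 2L,
            mz_range[1] < mz_range[2])
  structure(list(jitter_sd = jitter_sd, dropout_p = dropout_p,
                 n_decoys = as.integer(n_decoys), mz_range = mz_range,
                 seed = as.integer(seed),
                 exclude_near_true = exclude_near_true, tol = tol),
            class = "NoiseParams")
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an observed spectrum with a planted acetyl configuration
#'
#' Jitters, drops and decorates the theoretical ladder of a peptide /
#' acetyl configuration according to [noiseParams()]. The precursor peak
#' survives dropout and its m/z is stored unjittered so the acetyl count
#' remains inferable. Fully reproducible from the seed.
#'
#' @param p An [OdlPeptide-class].
#' @param config The planted [AcetylConfig-class].
#' @param params A [noiseParams()] list.
#' @param charges,maxDepth Passed to [theoreticalSpectrum()].
#' @return An [ObservedSpectrum-class]; attribute `"collisions"` counts
#'   decoys landing within `tol` of a true ion (0 under the default
#'   exclusion sampling).
#' @examples
#' p <- odlPeptide("NOSO-95C")
#' simulateSpectrum(p, acetylConfig(p, 2), noiseParams(seed = 7))
#' @export
simulateSpectrum <- function(p, config = acetylConfig(p),
                             params = noiseParams(),
                             charges = c(1L, 2L), maxDepth = 2L) {
  theo <- theoreticalSpectrum(p, config, charges, maxDepth)
  io <- ions(theo)
  if (!nrow(io)) stop("empty theoretical ladder")
  precMz <- precursorMzOf(p, config, 1L)
  .withSeed(params$seed, {
    isPrec <- io$series == "precursor"
    keep <- isPrec | stats::runif(nrow(io)) >= params$dropout_p
    mz <- io$mz[keep] + stats::rnorm(sum(keep), 0, params$jitter_sd)
    decoys <- numeric(0)
    collisions <- 0L
    if (params$n_decoys > 0L) {
      draw <- function(m) stats::runif(m, params$mz_range[1],
                                       params$mz_range[2])
      decoys <- draw(params$n_decoys)
      if (params$exclude_near_true) {
        for (it in 1:100) {
          bad <- vapply(decoys, function(d)
            any(abs(d - io$mz) <= params$tol), logical(1))
          if (!any(bad)) break
          decoys[bad] <- draw(sum(bad))
        }
        decoys <- decoys[!vapply(decoys, function(d)
          any(abs(d - io$mz) <= params$tol), logical(1))]
      } else {
        collisions <- sum(vapply(decoys, function(d)
          any(abs(d - io$mz) <= params$tol), logical(1)))
      }
    }
    allMz <- c(mz, decoys)
    out <- observedSpectrum(allMz, precursorMz = precMz,
                            precursorCharge = 1L)
    attr(out, "collisions") <- collisions
    out
  })
}

#' Localization-recovery benchmark
#'
#' Monte-Carlo harness: for every plantable residue-level configuration
#' of `k` acetyl groups and every row of a noise-parameter grid, spectra
#' are simulated and localized, and the fraction of replicates in which
#' the planted class is the unique top-ranked class is reported with a
#' binomial standard error.
#'
#' @param p An [OdlPeptide-class].
#' @param k Acetyl count to plant.
#' @param params_grid `data.frame` whose columns override [noiseParams()]
#'   fields (e.g. `jitter_sd`, `dropout_p`, `n_decoys`).
#' @param n_reps Replicates per cell (>= 1).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param tol Localization tolerance.
#' @return `data.frame` with one row per (config, grid row): the planted
#'   class, the grid parameters, `recovery` and `se`.
#' @export
benchmarkLocalization <- function(p, k, params_grid = data.frame(row = 1),
                                  n_reps = 20L, seed = 1L, tol = 0.5) {
  stopifnot(n_reps >= 1L)
  cfgs <- candidateConfigs(p, k)
  grid <- as.data.frame(params_grid)
  out <- list()
  cell <- 0L
  for (ci in seq_along(cfgs)) {
    for (gi in seq_len(nrow(grid))) {
      cell <- cell + 1L
      args <- as.list(grid[gi, intersect(names(grid),
        c("jitter_sd", "dropout_p", "n_decoys", "mz_range", "tol")),
        drop = FALSE])
      hits <- vapply(seq_len(n_reps), function(r) {
        pars <- do.call(noiseParams, c(args,
          list(seed = (seed * 10000L + cell * 100L + r) %% .Machine$integer.max)))
        obs <- simulateSpectrum(p, cfgs[[ci]], pars)
        rk <- localizeAcetyl(obs, p, k = k, tol = tol)
        top <- rk[rk$rank == 1L, , drop = FALSE]
        nrow(top) == 1L && top$class == names(cfgs)[ci]
      }, logical(1))
      rec <- mean(hits)
      out[[cell]] <- cbind(
        data.frame(class = names(cfgs)[ci], stringsAsFactors = FALSE),
        grid[gi, , drop = FALSE],
        data.frame(recovery = rec,
                   se = sqrt(rec * (1 - rec) / n_reps)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
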