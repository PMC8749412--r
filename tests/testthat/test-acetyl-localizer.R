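pC <- odlPeptide("NOSO-95C")

test_that("acetyl count is inferred from the precursor shift", {
  expect_equal(inferAcetylCount(observedSpectrum(100, precursorMz = 1307,
                                                 precursorCharge = 1), pC),
               1L, ignore_attr = TRUE)
  expect_equal(inferAcetylCount(observedSpectrum(100, precursorMz = 1265,
                                                 precursorCharge = 1), pC),
               0L, ignore_attr = TRUE)
  # doubly charged precursor of the triacetylated species
  expect_equal(inferAcetylCount(observedSpectrum(100, precursorMz = 696,
                                                 precursorCharge = 2), pC),
               3L, ignore_attr = TRUE)
  expect_error(inferAcetylCount(observedSpectrum(100, precursorMz = 1290,
                                                 precursorCharge = 1), pC),
               "off the acetyl lattice")
  expect_error(inferAcetylCount(observedSpectrum(100, precursorMz = 1000,
                                                 precursorCharge = 1), pC),
               "lighter")
  expect_error(inferAcetylCount(observedSpectrum(100), pC), "no usable|precursor")
})

test_that("peak matching is greedy, unique, and precision-aware", {
  obs <- readPeakList(odlFixture("table2_native.mgf"))
  theo <- theoreticalSpectrum(pC)
  m <- matchPeaks(obs, theo)
  expect_equal(nrow(m), 9L)                    # all native ions match
  expect_true(all(abs(m$error) <= 1.0))
  # a uniform +5 Da shift kills every match at the default tolerance
  pk <- peaks(obs)
  shifted <- observedSpectrum(pk$mz + 5, decimals = pk$decimals)
  expect_equal(nrow(matchPeaks(shifted, theo)), 0L)
  # duplicated observed peak: only one pairing is retained
  dup <- observedSpectrum(c(1136.7, 1136.7), decimals = c(1L, 1L))
  mdup <- matchPeaks(dup, theo)
  expect_equal(nrow(mdup), 1L)
  # integer-printed peaks get the widened 1.0 Da window
  intPeak <- observedSpectrum(1178, decimals = 0L)
  mono <- theoreticalSpectrum(pC, acetylConfig(pC, 2))
  expect_equal(nrow(matchPeaks(intPeak, mono)), 1L)
  # ... which a full-precision peak at the same distance would not get
  farPeak <- observedSpectrum(1178)
  expect_equal(nrow(matchPeaks(farPeak, mono)), 0L)
})

test_that("localization on the packaged ion lists recovers the published sites", {
  cases <- list(
    list(f = "table2_mono.mgf", k = 1, top = "{Dab(bOH)2}"),
    list(f = "table2_bi.mgf", k = 2, top = "{Dab(bOH)2,Dab(bOH)3}"),
    list(f = "table2_tri.mgf", k = 3, top = "{Dab(bOH)2,Dab(bOH)3,Lys10}"))
  for (cs in cases) {
    obs <- readPeakList(odlFixture(cs$f))
    rk <- localizeAcetyl(obs, pC)
    expect_equal(attr(rk, "k"), cs$k, label = cs$f)
    expect_equal(topConfig(rk), cs$top, label = cs$f)
    expect_false(rk$tied[1], label = cs$f)
  }
  p179 <- odlPeptide("NOSO-95179")
  obs179 <- readPeakList(odlFixture("noso95179_mono_synthetic.mgf"))
  rk179 <- localizeAcetyl(obs179, p179)
  expect_equal(topConfig(rk179), "{Dab(bOH)2}")
})

test_that("localization ranking equals an independent brute-force re-scoring", {
  # naive oracle: for each candidate enumerate matches with an O(n^2)
  # nearest-first scan, then order by (matches desc, error asc)
  naiveScore <- function(obs, theo, tol = 0.5) {
    pk <- peaks(obs); io <- ions(theo)
    ptol <- ifelse(!is.na(pk$decimals) & pk$decimals == 0, 1.0, tol)
    pairs <- NULL
    for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(io))) {
      e <- abs(pk$mz[i] - io$mz[j])
      if (e <= ptol[i]) pairs <- rbind(pairs, c(i, j, e))
    }
    if (is.null(pairs)) return(list(n = 0L, err = 0))
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    up <- ui <- integer(); n <- 0L; err <- 0
    for (r in seq_len(nrow(pairs))) {
      if (!(pairs[r, 1] %in% up) && !(pairs[r, 2] %in% ui)) {
        up <- c(up, pairs[r, 1]); ui <- c(ui, pairs[r, 2])
        n <- n + 1L; err <- err + pairs[r, 3]
      }
    }
    list(n = n, err = err)
  }
  for (f in c("table2_mono.mgf", "table2_tri.mgf")) {
    obs <- readPeakList(odlFixture(f))
    rk <- localizeAcetyl(obs, pC)
    k <- attr(rk, "k")
    cfgs <- candidateConfigs(pC, k)
    sc <- lapply(cfgs, function(cf)
      naiveScore(obs, theoreticalSpectrum(pC, cf)))
    n <- vapply(sc, `[[`, integer(1), "n")
    err <- vapply(sc, `[[`, numeric(1), "err")
    ord <- order(-n, err)
    expect_equal(rk$n_matched[match(names(cfgs), rk$class)],
                 unname(n), label = f)
    expect_equal(rk$class[1], names(cfgs)[ord[1]], label = f)
  }
})

test_that("mass-degenerate within-residue sites give identical spectra", {
  a <- theoreticalSpectrum(pC, acetylConfig(pC, 1, labels = "alpha"))
  b <- theoreticalSpectrum(pC, acetylConfig(pC, 1, labels = "epsilon"))
  expect_equal(ions(a)$mz, ions(b)$mz)
})

test_that("removing observed peaks never increases any candidate's match count", {
  obs <- readPeakList(odlFixture("table2_bi.mgf"))
  rkFull <- localizeAcetyl(obs, pC)
  pk <- peaks(obs)
  set.seed(5)
  keep <- sort(sample(nrow(pk), 5))
  sub <- observedSpectrum(pk$mz[keep], decimals = pk$decimals[keep],
                          precursorMz = precursorMz(obs),
                          precursorCharge = precursorCharge(obs))
  rkSub <- localizeAcetyl(sub, pC)
  m <- match(rkSub$class, rkFull$class)
  expect_true(all(rkSub$n_matched <= rkFull$n_matched[m]))
})

test_that("an empty peak list is flagged indeterminate", {
  empty <- observedSpectrum(numeric(), precursorMz = 1307,
                            precursorCharge = 1L)
  rk <- localizeAcetyl(empty, pC)
  expect_true(attr(rk, "indeterminate"))
  expect_true(all(rk$rank == 1L) && all(rk$tied))
})

test_that("annotation mirrors the published four-column layout", {
  obsBi <- readPeakList(odlFixture("table2_bi.mgf"))
  ann <- annotateSpectrum(obsBi, pC, acetylConfig(pC, c(2, 3)))
  y9 <- ann[ann$ion == "y9", ]
  expect_equal(y9$mz, 1062.6)
  expect_equal(y9$neutral_loss, "158")
  expect_equal(y9$attribution, "AcDab(bOH)2")
  expect_match(y9$assigned_structure, "^AcDab\\(bOH\\)-Gly")

  obsN <- readPeakList(odlFixture("table2_native.mgf"))
  annN <- annotateSpectrum(obsN, pC, acetylConfig(pC))
  b9 <- annN[annN$ion == "b9", ]
  expect_equal(b9$neutral_loss, "216 (128 + 88)")
  expect_equal(b9$attribution, "Lys10-Dbt11")
  expect_false(any(grepl("Ac", annN$assigned_structure)))

  # the inconsistent printed mono-block y5 lands in the unassigned trailer
  obsM <- readPeakList(odlFixture("table2_mono.mgf"))
  annM <- annotateSpectrum(obsM, pC, acetylConfig(pC, 2))
  expect_true(635.9 %in% annM$mz[annM$ion == "unassigned"])
})

test_that("species quantification computes fractions and pairwise ratios", {
  q <- quantifySpecies(c(bi = 100, tri = 4))
  expect_equal(q$ratios$ratio[q$ratios$num == "bi"], 25)
  q2 <- quantifySpecies(c(native = 72, mono = 28))
  expect_equal(q2$table$fraction[q2$table$species == "native"], 0.72)
  expect_equal(sum(q2$table$fraction), 1)
  q3 <- quantifySpecies(c(mono = 10))
  expect_equal(nrow(q3$ratios), 0L)
  expect_error(quantifySpecies(c(a = 0, b = 0)), "zero")
  expect_error(quantifySpecies(c(a = -1, b = 2)), "non-negative")
})
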