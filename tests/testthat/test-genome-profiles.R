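test_that("ANI converts to distance with percent auto-scaling", {
  expect_equal(distanceFromANI(0.94), 0.06)
  expect_equal(distanceFromANI(94), 0.06)
  expect_equal(distanceFromANI(1.0), 0)
  expect_error(distanceFromANI(107), "out of range")
  expect_error(distanceFromANI(-0.1), "negative")
  m <- matrix(c(1, 0.95, 0.95, 1), 2)
  expect_equal(distanceFromANI(m), 1 - m)
})

test_that("species clustering is inclusive at the cutoff and equals brute force", {
  mk <- function(v, labs) {
    d <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
    d[lower.tri(d)] <- v; d[upper.tri(d)] <- t(d)[upper.tri(d)]; d
  }
  two <- mk(0.05, c("A", "B"))
  expect_equal(length(speciesClusters(two)), 1L)
  expect_equal(length(speciesClusters(mk(0.061, c("A", "B")))), 2L)
  chain <- mk(c(0.05, 0.10, 0.05), c("A", "B", "C"))
  expect_equal(speciesClusters(chain), list(c("A", "B", "C")))

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    labs <- paste0("g", sample(n))
    d <- mk(runif(n * (n - 1) / 2, 0, 0.15), labs)
    expect_equal(speciesClusters(d), oracleComponents(d, 0.06))
    # label-order invariance
    perm <- sample(n)
    expect_equal(speciesClusters(d[perm, perm]), speciesClusters(d))
  }
})

test_that("neighbor joining recovers random additive matrices exactly", {
  set.seed(17)
  for (n in 4:8) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- njTree(d)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
  expect_error(njTree(matrix(0, 2, 2)), "3 taxa")
})

test_that("three-taxon NJ matches the closed-form three-point branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  tip <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(tip[["A"]], (2 + 3 - 4) / 2)   # 0.5
  expect_equal(tip[["B"]], (2 + 4 - 3) / 2)   # 1.5
  expect_equal(tip[["C"]], (3 + 4 - 2) / 2)   # 2.5
})

test_that("on ultrametric input NJ and UPGMA agree in topology", {
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (rep in 1:5) {
    tr <- ape::rcoal(6)
    d <- ape::cophenetic.phylo(tr)
    expect_equal(phangorn::RF.dist(ape::unroot(njTree(d)),
                                   ape::unroot(upgmaTree(d))), 0)
  }
})

test_that("UPGMA reproduces ultrametric inputs and yields ultrametric output", {
  set.seed(29)
  for (rep in 1:5) {
    tr <- ape::rcoal(sample(4:8, 1))
    d <- ape::cophenetic.phylo(tr)
    u <- upgmaTree(d)
    expect_equal(ape::cophenetic.phylo(u)[rownames(d), colnames(d)], d,
                 tolerance = 1e-6)
  }
  # arbitrary input: the cophenetic matrix must satisfy the ultrametric
  # three-point condition
  mkFull <- function(n) {
    d <- matrix(runif(n * n, 0.1, 1), n); d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n]); d
  }
  d <- mkFull(6)
  cc <- ape::cophenetic.phylo(upgmaTree(d))
  labs <- rownames(cc)
  for (i in labs) for (j in labs) for (k in labs)
    expect_lte(cc[i, j], max(cc[i, k], cc[j, k]) + 1e-9)
})

test_that("UPGMA merges lexicographically smallest pairs on ties", {
  labs <- c("C", "A", "B")
  d <- matrix(1, 3, 3, dimnames = list(labs, labs)); diag(d) <- 0
  tr <- upgmaTree(d)
  # all distances tie: A and B must merge first, C joins last
  pair <- ape::extract.clade(tr, ape::Ntip(tr) + 2)$tip.label
  expect_setequal(pair, c("A", "B"))
  # two-taxon base case: one node at half the distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgmaTree(d2)
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))
  expect_error(upgmaTree(matrix(0, 1, 1)), "2 taxa")
})

test_that("UPGMA agrees with the reference average-linkage implementation", {
  skip_if_not_installed("phangorn")
  set.seed(59)
  for (rep in 1:5) {
    n <- 7
    d <- matrix(runif(n * n, 0.2, 1), n); d <- (d + t(d)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    mine <- ape::cophenetic.phylo(upgmaTree(d))
    ref <- ape::cophenetic.phylo(phangorn::upgma(as.dist(d)))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-8)
  }
})

test_that("ortholog calls honor inclusive thresholds and are monotone", {
  expect_true(orthologCall(70, 80, 100, 100))
  expect_false(orthologCall(69.9, 100, 100, 100))
  expect_true(orthologCall(100, 100, 100, 100))
  expect_false(orthologCall(90, 79, 100, 100))
  # minLrap uses the longer sequence by default
  expect_false(orthologCall(90, 80, 100, 120))   # 80/120 = 66.7%
  expect_true(orthologCall(90, 96, 100, 120))    # 96/120 = 80%
  expect_true(orthologCall(90, 80, 100, 120, coverage_of = "query"))
  expect_error(orthologCall(50, 10, 0, 100), "positive")
  # monotonicity in identity and coverage
  set.seed(3)
  id <- runif(50, 0, 100); al <- runif(50, 1, 200)
  base <- orthologCall(id, al, 200, 200)
  expect_true(all(orthologCall(pmin(id + 10, 100), al, 200, 200) >= base))
  expect_true(all(orthologCall(id, pmin(al + 40, 200), 200, 200) >= base))
})

test_that("presence calls use a strict max-probe threshold", {
  s <- rbind(A = c(1200, 300), B = c(900, 900), C = c(1000, 10))
  pc <- presenceCall(s, targets = c("odl1", "odl1"))
  expect_equal(pc[, "odl1"], c(A = 1L, B = 0L, C = 0L))  # 1000 is absent
  s2 <- cbind(s, oat = c(1500, 1001, 0))
  pc2 <- presenceCall(s2, targets = c("odl1", "odl1", "oatA"))
  expect_equal(pc2[, "oatA"], c(A = 1L, B = 1L, C = 0L))
  expect_error(presenceCall(s, targets = "one"), "per probe")
  expect_error(presenceCall(-s, targets = c("x", "x")), "non-negative")
})

test_that("binary Gower similarity is simple matching", {
  m <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0), C = c(1, 1, 0, 0),
             D = c(0, 0, 1, 1))
  sim <- gowerBinarySimilarity(m)
  expect_equal(sim["A", "C"], 1)
  expect_equal(sim["A", "D"], 0)
  expect_equal(sim["A", "B"], 0.5)
  expect_error(gowerBinarySimilarity(m * 2), "binary")
  skip_if_not_installed("vegan")
  set.seed(71)
  bm <- matrix(rbinom(60, 1, 0.5), nrow = 5,
               dimnames = list(paste0("s", 1:5), NULL))
  ref <- as.matrix(vegan::vegdist(bm, method = "gower"))
  expect_equal(1 - gowerBinarySimilarity(bm), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("distance-matrix validation rejects malformed input", {
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgmaTree(neg), "non-negative")
  nonzero <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(speciesClusters(nonzero), "diagonal")
})
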