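#' @include atoms.R
NULL

## Genomic-distribution calculus: ANI distances, species clustering at a
## fixed cutoff, distance trees (NJ via ape, UPGMA with a deterministic
## lexicographic tie-break), ortholog thresholding, and microarray-style
## presence/absence profiling.

.checkDistanceMatrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels disagree")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  d
}

#' ANI to distance
#'
#' Converts average nucleotide identity to the genome distance
#' D = 1 - ANI. Percent inputs (values above 1, up to 100) are
#' auto-scaled to fractions.
#'
#' @param ani Numeric scalar, vector or matrix of ANI values, as
#'   fractions in [0, 1] or percentages in (1, 100].
#' @return D = 1 - ANI, same shape as the input.
#' @examples
#' distanceFromANI(0.94)   # 0.06, the species-boundary distance
#' distanceFromANI(94)     # same, percent input
#' @export
distanceFromANI <- function(ani) {
  if (any(!is.finite(ani))) stop("ANI values must be finite")
  if (any(ani < 0)) stop("ANI cannot be negative")
  if (any(ani > 1)) {
    if (any(ani > 100)) stop("ANI out of range (max 100%)")
    ani <- ani / 100
  }
  1 - ani
}

#' Species clusters at a distance cutoff
#'
#' Single-linkage components at a threshold: two genomes are connected
#' when their distance is less than or equal to `cutoff` (default 0.06,
#' i.e. about 94% ANI, the standard species boundary), and clusters are
#' the connected components of that graph.
#'
#' @param dm Square symmetric distance matrix with labels.
#' @param cutoff Inclusive distance threshold.
#' @return List of character vectors (one per cluster, members sorted),
#'   ordered by first member.
#' @export
speciesClusters <- function(dm, cutoff = 0.06) {
  d <- .checkDistanceMatrix(dm)
  n <- nrow(d)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v]) next
        comp[v] <- cur
        queue <- c(queue, which(d[v, ] <= cutoff & comp == 0L))
      }
    }
  }
  out <- lapply(split(rownames(d), comp), sort)
  names(out) <- NULL
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a labelled distance matrix (delegating
#' to \pkg{ape}). Additive matrices are recovered exactly. Negative
#' branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with a warning.
#'
#' @param dm Square symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(dm) {
  d <- .checkDistanceMatrix(dm)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' UPGMA tree
#'
#' Average-linkage agglomerative clustering producing an ultrametric
#' dendrogram; node heights are half the cophenetic distance. Merge ties
#' are broken deterministically in favour of the pair whose clusters
#' carry the lexicographically smallest member labels.
#'
#' @param dm Square symmetric distance matrix (>= 2 taxa).
#' @return A rooted ultrametric `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a","b"), c("a","b")))
#' upgmaTree(d)
#' @export
upgmaTree <- function(dm) {
  d <- .checkDistanceMatrix(dm)
  n <- nrow(d)
  if (n < 2L) stop("UPGMA needs at least 2 taxa")
  labs <- rownames(d)
  ## active clusters: newick fragment, size, height, smallest member label
  nwk <- labs
  size <- rep(1L, n)
  height <- rep(0, n)
  lead <- labs
  D <- d
  active <- seq_len(n)
  while (length(active) > 1L) {
    ## minimum average distance; lexicographic tie-break on member labels
    best <- NULL
    for (a in seq_along(active)) for (b in seq_len(a - 1L)) {
      i <- active[a]; j <- active[b]
      dij <- D[i, j]
      key <- sort(c(lead[i], lead[j]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    newNwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], h - height[i],
                      nwk[j], h - height[j])
    ## UPGMA update: size-weighted average to every other cluster
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    nwk[i] <- newNwk
    size[i] <- size[i] + size[j]
    height[i] <- h
    lead[i] <- min(best$key)
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

#' Ortholog call from pairwise-alignment statistics
#'
#' A hit is an ortholog when percent identity meets `id_min` (default
#' >= 70) and the alignment covers at least `minlrap_min` percent
#' (default >= 80) of the reference length. The coverage denominator
#' ("minLrap") defaults to the longer of the two sequences, the
#' conservative reading of a minimum length-ratio; query- or
#' subject-length denominators are available.
#'
#' @param identity Percent identity (0..100), vectorized.
#' @param alignment_length,query_length,subject_length Alignment and
#'   sequence lengths in residues (positive).
#' @param id_min,minlrap_min Inclusive thresholds in percent.
#' @param coverage_of Denominator choice: `"longer"` (default),
#'   `"query"`, `"subject"`.
#' @return Logical vector.
#' @examples
#' orthologCall(70, 80, 100, 100)   # TRUE: thresholds are inclusive
#' @export
orthologCall <- function(identity, alignment_length, query_length,
                         subject_length, id_min = 70, minlrap_min = 80,
                         coverage_of = c("longer", "query", "subject")) {
  coverage_of <- match.arg(coverage_of)
  if (any(identity < 0 | identity > 100))
    stop("identity must be within 0..100")
  if (any(query_length <= 0) || any(subject_length <= 0))
    stop("sequence lengths must be positive")
  if (any(alignment_length <= 0))
    stop("alignment length must be positive")
  den <- switch(coverage_of,
                longer = pmax(query_length, subject_length),
                query = query_length,
                subject = subject_length)
  coverage <- 100 * alignment_length / den
  identity >= id_min & coverage >= minlrap_min
}

#' @rdname orthologCall
#' @param hits A hit table as returned by [readHitTable()].
#' @param ... Passed on to `orthologCall()`.
#' @export
callOrthologs <- function(hits, ...) {
  hits$ortholog <- orthologCall(hits$percent_identity,
                                hits$alignment_length, hits$query_length,
                                hits$subject_length, ...)
  hits
}

#' Presence calls from probe signals
#'
#' A target sequence is called present in a strain when the hybridization
#' signal of at least one of its probes strictly exceeds the threshold
#' (default 1000).
#'
#' @param signals Non-negative numeric matrix, strains x probes.
#' @param targets Character/factor of length `ncol(signals)` assigning
#'   each probe to a target sequence.
#' @param threshold Strict signal threshold.
#' @return Binary integer matrix, strains x targets.
#' @examples
#' s <- rbind(A = c(1200, 300), B = c(900, 900))
#' presenceCall(s, targets = c("odl1", "odl1"))
#' @export
presenceCall <- function(signals, targets = colnames(signals),
                         threshold = 1000) {
  signals <- as.matrix(signals)
  if (any(signals < 0)) stop("probe signals must be non-negative")
  if (is.null(targets)) stop("probe-to-target grouping required")
  if (length(targets) != ncol(signals))
    stop("'targets' must have one entry per probe column")
  targets <- as.character(targets)
  utab <- unique(targets)
  out <- vapply(utab, function(tg) {
    sub <- signals[, targets == tg, drop = FALSE]
    if (!ncol(sub)) stop("target with zero probes: ", tg)
    as.integer(apply(sub, 1L, max) > threshold)
  }, integer(nrow(signals)))
  out <- matrix(out, nrow = nrow(signals),
                dimnames = list(rownames(signals), utab))
  out
}

#' Gower similarity for binary profiles
#'
#' For symmetric binary data the Gower coefficient reduces to simple
#' matching: the fraction of targets on which two strains agree.
#'
#' @param profiles Binary matrix, strains x targets.
#' @return Symmetric similarity matrix (1 on the diagonal); the
#'   corresponding distance is `1 - similarity`.
#' @examples
#' m <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0))
#' gowerBinarySimilarity(m)["A", "B"]   # 0.5
#' @export
gowerBinarySimilarity <- function(profiles) {
  m <- as.matrix(profiles)
  if (!ncol(m)) stop("profile matrix has zero targets")
  if (!all(m %in% c(0, 1))) stop("profiles must be binary (0/1)")
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(n))
  sim <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    sim[i, j] <- mean(m[i, ] == m[j, ])
  sim
}
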