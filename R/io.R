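#' @include localize.R
NULL

.decimalsOf <- function(token) {
  has <- grepl(".", token, fixed = TRUE)
  ifelse(has, nchar(sub("^[^.]*\\.", "", token)), 0L)
}

#' Read an observed peak list
#'
#' Reads MGF (`BEGIN IONS` / `PEPMASS` / `CHARGE` honoured) or
#' two-column `mz,intensity` CSV peak lists. The printed decimal
#' precision of each m/z is recorded so that matching can widen its
#' window for integer-printed peaks. Malformed records raise errors
#' naming the offending line.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mgf"` or `"csv"`.
#' @param precursorMz,precursorCharge Used for CSV input, which carries
#'   no precursor header.
#' @return An [ObservedSpectrum-class].
#' @examples
#' readPeakList(odlFixture("table2_native.mgf"))
#' @export
readPeakList <- function(path, format = c("auto", "mgf", "csv"),
                         precursorMz = NA_real_,
                         precursorCharge = NA_integer_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  if (format == "mgf") .readMgf(path) else
    .readPeakCsv(path, precursorMz, precursorCharge)
}

.numOrStop <- function(token, path, lineno, what) {
  x <- suppressWarnings(as.numeric(token))
  if (is.na(x))
    stop(basename(path), " line ", lineno, ": non-numeric ", what,
         " '", token, "'")
  x
}

.readMgf <- function(path) {
  lines <- readLines(path)
  inIons <- FALSE
  mz <- numeric(); int <- numeric(); dec <- integer()
  pep <- NA_real_; chg <- NA_integer_
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (!nzchar(l) || startsWith(l, "#")) next
    if (l == "BEGIN IONS") { inIons <- TRUE; next }
    if (l == "END IONS") { inIons <- FALSE; next }
    if (grepl("^[A-Z]+=", l)) {
      key <- sub("=.*", "", l); val <- sub("^[A-Z]+=", "", l)
      if (key == "PEPMASS") {
        tok <- strsplit(val, "[ \t]+")[[1]][1]
        pep <- .numOrStop(tok, path, ln, "PEPMASS")
      } else if (key == "CHARGE") {
        chg <- as.integer(sub("\\+$", "", val))
        if (is.na(chg)) stop(basename(path), " line ", ln,
                             ": unparseable CHARGE '", val, "'")
      }
      next
    }
    if (!inIons) next
    tok <- strsplit(l, "[ \t]+")[[1]]
    mz <- c(mz, .numOrStop(tok[1], path, ln, "m/z"))
    int <- c(int, if (length(tok) > 1L)
      .numOrStop(tok[2], path, ln, "intensity") else 1)
    dec <- c(dec, .decimalsOf(tok[1]))
  }
  if (!length(mz)) stop(basename(path), ": no peaks found")
  observedSpectrum(mz, int, precursorMz = pep, precursorCharge = chg,
                   decimals = dec)
}

.readPeakCsv <- function(path, precursorMz, precursorCharge) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (grepl("^\\s*mz\\s*,", lines[1], ignore.case = TRUE)) start <- 2L
  mz <- numeric(); int <- numeric(); dec <- integer()
  for (ln in seq(start, length(lines))) {
    tok <- trimws(strsplit(lines[ln], ",", fixed = TRUE)[[1]])
    mz <- c(mz, .numOrStop(tok[1], path, ln, "m/z"))
    int <- c(int, if (length(tok) > 1L && nzchar(tok[2]))
      .numOrStop(tok[2], path, ln, "intensity") else 1)
    dec <- c(dec, .decimalsOf(tok[1]))
  }
  observedSpectrum(mz, int, precursorMz = precursorMz,
                   precursorCharge = precursorCharge, decimals = dec)
}

#' Write a peak list or theoretical ladder as MGF
#'
#' @param x An [ObservedSpectrum-class] or [TheoreticalSpectrum-class].
#' @param path Output path.
#' @param title `TITLE` line content.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(x, path, title = "odltools spectrum") {
  if (is(x, "TheoreticalSpectrum")) {
    io <- ions(x)
    mz <- io$mz; int <- rep(1, nrow(io))
    pep <- precursorMzOf(x@peptide, x@config, 1L); chg <- 1L
  } else {
    pk <- peaks(x)
    mz <- pk$mz; int <- pk$intensity
    pep <- precursorMz(x); chg <- precursorCharge(x)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("BEGIN IONS", con)
  writeLines(paste0("TITLE=", title), con)
  if (!is.na(pep)) writeLines(sprintf("PEPMASS=%.5f", pep), con)
  if (!is.na(chg)) writeLines(sprintf("CHARGE=%d+", chg), con)
  writeLines(sprintf("%.5f %.6g", mz, int), con)
  writeLines("END IONS", con)
  invisible(path)
}

#' Export a theoretical spectrum as a delimited table
#'
#' @param theo A [TheoreticalSpectrum-class].
#' @param path Output path (tab-delimited: series, index, charge, mz,
#'   label).
#' @return Invisibly, `path`.
#' @export
writeIonTable <- function(theo, path) {
  io <- ions(theo)
  utils::write.table(io[c("series", "index", "charge", "mz", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square labelled distance matrix
#'
#' Tab-delimited square matrix with a header row and a label column
#' (PHYLIP-square style with labels).
#'
#' @param path File path.
#' @return `readDistanceMatrix`: a labelled numeric matrix (validated
#'   symmetric, zero diagonal).
#' @export
readDistanceMatrix <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  .checkDistanceMatrix(as.matrix(tab))
}

#' @rdname readDistanceMatrix
#' @param d Labelled square matrix.
#' @export
writeDistanceMatrix <- function(d, path) {
  d <- .checkDistanceMatrix(d)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a tabular alignment-hit file
#'
#' BLAST-tabular-style delimited text with columns query id, subject id,
#' percent identity, alignment length, query length, subject length
#' (header optional; extra columns ignored when a header names the six
#' required fields).
#'
#' @param path File path.
#' @return `data.frame` with columns `query`, `subject`,
#'   `percent_identity`, `alignment_length`, `query_length`,
#'   `subject_length`.
#' @export
readHitTable <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("identity", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (hasHeader) {
    need <- c("query", "subject", "percent_identity", "alignment_length",
              "query_length", "subject_length")
    if (!all(need %in% names(tab)))
      stop("hit table header must name: ", paste(need, collapse = ", "))
    tab <- tab[need]
  } else {
    if (ncol(tab) < 6L)
      stop("headerless hit table needs 6 columns: query, subject, ",
           "identity, alignment length, query length, subject length")
    tab <- tab[, 1:6]
    names(tab) <- c("query", "subject", "percent_identity",
                    "alignment_length", "query_length", "subject_length")
  }
  tab
}

#' Paths of packaged fixtures
#'
#' Access to the peak lists shipped with the package: the four MS/MS
#' ion tables for native, mono-, bi- and triacetylated NOSO-95C
#' (`table2_native.mgf`, `table2_mono.mgf`, `table2_bi.mgf`,
#' `table2_tri.mgf`) and a synthetic stand-in peak list for the
#' monoacetylated NOSO-95179 analog
#' (`noso95179_mono_synthetic.mgf`).
#'
#' @param name Fixture file name; with no argument, lists available
#'   fixtures.
#' @return File path (or vector of fixture names).
#' @export
odlFixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "odltools", mustWork = TRUE)
  if (is.null(name))
    return(list.files(dir, pattern = "\\.mgf$"))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no packaged fixture '", name, "'")
  path
}
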