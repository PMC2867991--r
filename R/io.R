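#' Read a multichannel recording from CSV
#'
#' The exchange format is deliberately strict: comma-separated, '.' decimal
#' point, a single header row naming the leads, time running down the rows,
#' and no time column (the sampling rate is supplied by the caller). Blank
#' lines inside the body, ragged rows and non-numeric cells are format errors
#' reported with their line number.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @return A [Recording-class] with leads in header order and `N` equal to
#'   the number of data rows.
#' @seealso [writeRecordingCSV()]
#' @export
readRecordingCSV <- function(path, fs) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # tolerate a single trailing newline artifact
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L)
    stop(sprintf("format error in %s: need a header and at least one data row",
                 path))
  leads <- trimws(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
  nl <- length(leads)
  body <- lines[-1L]
  n <- length(body)
  samples <- matrix(NA_real_, nrow = nl, ncol = n)
  for (i in seq_len(n)) {
    ln <- i + 1L
    if (!nzchar(trimws(body[i])))
      stop(sprintf("format error in %s at line %d: blank line in body",
                   path, ln))
    cells <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(cells) != nl)
      stop(sprintf(
        "format error in %s at line %d: %d fields, expected %d (ragged row)",
        path, ln, length(cells), nl))
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop(sprintf("format error in %s at line %d: non-numeric cell '%s'",
                   path, ln, cells[which(is.na(vals))[1L]]))
    samples[, i] <- vals
  }
  Recording(samples, fs = fs, leadLabels = leads,
            meta = sprintf("read from %s", path))
}

#' Write a Recording to CSV
#'
#' Amplitudes are written with a full 17-significant-digit decimal
#' representation so that `readRecordingCSV(writeRecordingCSV(rec))`
#' reproduces the samples bit-exactly.
#'
#' @param rec a [Recording-class].
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  validObject(rec)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(rec@leadLabels, collapse = ","), con)
  body <- apply(rec@samples, 2L,
                function(col) paste(sprintf("%.17g", col), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Rank leads by electro-oculogram contamination
#'
#' Orders the non-EOG leads from least to most contaminated, measured as the
#' absolute Pearson correlation of each lead's raw amplitudes with the EOG
#' channel. Ties keep the original lead order. Downstream feature extraction
#' restricts itself to the least-contaminated leads.
#'
#' @param rec a [Recording-class].
#' @param eogLabel name of the EOG lead (default `"EOG"`).
#' @return Character vector of the non-EOG lead names, least contaminated
#'   first.
#' @examples
#' rec <- syntheticRecording(taskClassSpec("relax"), seed = 1)
#' rankLeadsByEOG(rec)
#' @export
rankLeadsByEOG <- function(rec, eogLabel = "EOG") {
  stopifnot(is(rec, "Recording"))
  if (!eogLabel %in% rec@leadLabels)
    stop(sprintf("EOG lead '%s' not present in recording", eogLabel))
  eog <- getLead(rec, eogLabel)
  others <- setdiff(rec@leadLabels, eogLabel)
  r <- vapply(others, function(ld) {
    v <- suppressWarnings(cor(getLead(rec, ld), eog))
    if (is.na(v)) 0 else abs(v)
  }, numeric(1))
  others[order(r, seq_along(others))]
}
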