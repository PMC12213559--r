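## Reader for the UCI alcoholism EEG trial text dialect and conversion of
## parsed records into the SegmentSet container.

uciError <- function(reason, message, line = NA_integer_) {
  structure(
    class = c("uciTrialError", "error", "condition"),
    list(message = message, call = NULL, reason = reason, line = line))
}

#' Reason code of a rejected UCI trial
#'
#' @param e a condition raised by [readUciTrial()].
#' @return the reason code ("empty_file", "trial_error", "parse_error") or
#'   NA for foreign conditions.
#' @export
uciRejectReason <- function(e) {
  if (inherits(e, "uciTrialError")) e$reason else NA_character_
}

#' Parse one trial in the UCI alcoholism EEG text dialect
#'
#' The dialect: comment header lines introduced by `#` (the first naming
#' the subject file, e.g. `co2a0000364`; a later one carrying the stimulus
#' condition and trial number, e.g. `# S1 obj , trial 0`), followed by
#' whitespace-separated data records `channel-number channel-label
#' sample-index value`.  Channels labeled X, Y or nd are dropped; trials
#' whose condition header carries an `err` marker are rejected with reason
#' code `trial_error`; empty streams are rejected with `empty_file`;
#' malformed lines raise `parse_error` naming the line number.  The
#' subject's group is decoded from the 4th character of the subject
#' identifier (`a` = alcoholic = 1, `c` = control = 0).
#'
#' @param path file path, connection, or a character vector of lines.
#' @param samplingRate sampling rate of the corpus in Hz.
#' @return a [UCITrialRecord-class].
#' @seealso [uciRejectReason()] to classify rejections, [toSegmentSet()]
#'   to stack parsed trials.
#' @export
readUciTrial <- function(path, samplingRate = 256) {
  lines <- if (is.character(path) &&
               (length(path) != 1L || !file.exists(path))) path
           else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) stop(uciError("empty_file", "empty UCI trial stream"))
  headerIdx <- which(startsWith(lines, "#"))
  dataIdx <- which(keep & !startsWith(lines, "#"))
  if (!length(dataIdx)) {
    stop(uciError("empty_file", "UCI trial stream has no data records"))
  }
  header <- sub("^#\\s*", "", lines[headerIdx])
  subjectId <- if (length(header)) strsplit(header[1], "\\s+")[[1]][1] else ""
  condLine <- grep(",\\s*trial\\s+[0-9]+", header, value = TRUE)
  condition <- if (length(condLine)) {
    trimws(sub(",.*$", "", condLine[1]))
  } else ""
  trialNumber <- if (length(condLine)) {
    num <- regmatches(condLine[1], regexpr("trial\\s+[0-9]+", condLine[1]))
    if (length(num)) as.integer(sub("trial\\s+", "", num)) else NA_integer_
  } else NA_integer_
  if (any(grepl("\\berr\\b", header))) {
    stop(uciError("trial_error",
                  sprintf("trial %s marked as error in '%s'",
                          trialNumber, subjectId)))
  }
  ## data records: channel-number channel-label sample-index value
  fields <- strsplit(lines[dataIdx], "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != 4L)
  if (length(bad)) {
    stop(uciError("parse_error",
                  sprintf("malformed record at line %d (expected 4 fields, got %d)",
                          dataIdx[bad[1]], nf[bad[1]]),
                  line = dataIdx[bad[1]]))
  }
  rec <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  vals <- suppressWarnings(as.numeric(rec[, 4]))
  sampleIdx <- suppressWarnings(as.integer(rec[, 3]))
  badNum <- which(is.na(vals) | is.na(sampleIdx))
  if (length(badNum)) {
    stop(uciError("parse_error",
                  sprintf("non-numeric record at line %d",
                          dataIdx[badNum[1]]),
                  line = dataIdx[badNum[1]]))
  }
  chan <- rec[, 2]
  keepCh <- !(tolower(chan) %in% c("x", "y", "nd"))
  if (!any(keepCh)) {
    stop(uciError("parse_error", "no retained channels after exclusions"))
  }
  chanNames <- unique(chan[keepCh])
  perChan <- split(vals[keepCh], factor(chan[keepCh], levels = chanNames))
  counts <- lengths(perChan)
  if (length(unique(counts)) != 1L) {
    stop(uciError("parse_error",
                  "retained channels have unequal sample counts"))
  }
  dat <- do.call(rbind, perChan)
  label <- if (nchar(subjectId) >= 4L && substr(subjectId, 4, 4) == "a") 1L
           else 0L
  new("UCITrialRecord", subjectId = subjectId,
      trialNumber = if (is.na(trialNumber)) 0L else trialNumber,
      condition = condition, label = label, data = dat,
      channelNames = chanNames, samplingRate = as.numeric(samplingRate))
}

#' Stack parsed trials or records into a SegmentSet
#'
#' Each [UCITrialRecord-class] or [EEGRecord-class] becomes one segment of
#' the (N x C x 1 x T) container; labels and subject identifiers are
#' preserved in input order.  All inputs must agree in channel count and
#' sample count.
#'
#' @param records list of [UCITrialRecord-class] and/or
#'   [EEGRecord-class] objects.
#' @return a [SegmentSet-class].
#' @export
toSegmentSet <- function(records) {
  if (!length(records)) stop("no records to stack")
  getDat <- function(r) r@data
  dims <- vapply(records, function(r) dim(getDat(r)), integer(2))
  if (length(unique(dims[1, ])) != 1L) {
    stop("heterogeneous channel counts: ",
         paste(unique(dims[1, ]), collapse = ", "))
  }
  if (length(unique(dims[2, ])) != 1L) {
    stop("heterogeneous sample counts: ",
         paste(unique(dims[2, ]), collapse = ", "))
  }
  C <- dims[1, 1]; T <- dims[2, 1]
  N <- length(records)
  seg <- array(0, dim = c(N, C, 1L, T))
  labs <- integer(N)
  subj <- character(N)
  for (i in seq_len(N)) {
    r <- records[[i]]
    seg[i, , 1L, ] <- getDat(r)
    labs[i] <- r@label
    subj[i] <- if (is(r, "UCITrialRecord")) r@subjectId else r@subjectId
  }
  fs <- records[[1]]@samplingRate
  segmentSet(seg, labs, subj, fs)
}
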