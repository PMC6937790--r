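#' Label a recording from umbilical-artery pH
#'
#' Umbilical-artery pH measured after delivery is the objective marker of
#' fetal acidemia: a pH below the threshold (7.15 by default) is
#' pathological, a pH greater than or equal to it is normal. Values outside
#' the plausible clinical band 6.5-7.6 trigger a warning but are still
#' labelled.
#'
#' @param ph finite numeric pH value.
#' @param threshold decision threshold on the pH scale.
#' @return `"pathological"` if `ph < threshold`, else `"normal"`.
#' @examples
#' labelFromPh(7.10)  # pathological
#' labelFromPh(7.15)  # the boundary value is normal
#' @export
labelFromPh <- function(ph, threshold = 7.15) {
  if (length(ph) != 1 || !is.finite(ph))
    stop("labelFromPh: pH is absent or not finite; supply an explicit label")
  if (ph < 6.5 || ph > 7.6)
    warning(sprintf("pH %.2f is outside the plausible clinical range 6.5-7.6", ph))
  if (ph < threshold) "pathological" else "normal"
}

#' Read a fetal heart-rate record
#'
#' Two dialects are supported. `"csv"` is the package's plain-text fixture
#' format: `# key=value` comment lines (e.g. `# ph=7.20`, `# fs=4`) followed
#' by one bpm sample per line. `"wfdb"` reads a PhysioNet WFDB record
#' (`.hea` text header plus format-16 binary `.dat`): the first channel whose
#' description contains "FHR" is taken as the heart-rate channel, digital
#' values are converted with the per-channel gain and baseline, and the pH is
#' parsed from `#pH <value>` comment lines of the header.
#'
#' @param path path to the CSV fixture or to the WFDB record (with or
#'   without the `.hea` extension).
#' @param dialect `"csv"` or `"wfdb"`.
#' @return An [FHRRecord-class]; its label is derived from the pH when
#'   present, otherwise `"unknown"`.
#' @seealso [writeRecordCSV()] for the round-trip writer.
#' @export
readRecord <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  switch(dialect, csv = .readRecordCSV(path), wfdb = .readRecordWFDB(path))
}

.parseHeaderComments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*[=: ]\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

.readRecordCSV <- function(path) {
  if (!file.exists(path)) stop("readRecord: file not found: ", path)
  lines <- readLines(path)
  isComment <- grepl("^#", lines)
  meta <- .parseHeaderComments(lines[isComment])
  body <- lines[!isComment & nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) stop("readRecord: non-numeric samples in ", path)
  ph <- .findPh(meta)
  fs <- meta[["fs"]] %||% 4
  id <- as.character(meta[["id"]] %||% sub("\\.[^.]*$", "", basename(path)))
  label <- meta[["label"]]
  if (!is.null(label) && !label %in% .LABELS) label <- NULL
  meta[c("fs", "id", "label")] <- NULL
  FHRRecord(id, vals, fs = fs, ph = ph, label = label, metadata = meta)
}

.findPh <- function(meta) {
  for (k in names(meta)) {
    if (tolower(k) == "ph" && is.numeric(meta[[k]])) return(meta[[k]])
  }
  NA_real_
}

# Minimal WFDB reader: text .hea header + interleaved little-endian int16
# .dat (format 16).  Enough for cardiotocography records; anything else
# raises a format error.
.readRecordWFDB <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("readRecord: header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[nzchar(trimws(lines))]
  comments <- lines[grepl("^#", lines)]
  spec <- lines[!grepl("^#", lines)]
  rec <- strsplit(trimws(spec[1]), "\\s+")[[1]]
  recName <- rec[1]; nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(rec[3]) else 4
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1) stop("readRecord: malformed WFDB header")
  sig <- lapply(spec[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*", "", f[2])
    gainSpec <- f[3]
    gain <- as.numeric(sub("\\(.*", "", gainSpec))
    baseline <- if (grepl("\\(", gainSpec))
      as.numeric(sub(".*\\((-?[0-9.]+)\\).*", "\\1", gainSpec)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = fmt, gain = ifelse(is.na(gain) || gain == 0, 200, gain),
         baseline = baseline, desc = desc)
  })
  fhrIdx <- which(vapply(sig, function(s) grepl("FHR", s$desc, ignore.case = TRUE), TRUE))
  if (length(fhrIdx) == 0)
    stop("readRecord: no FHR channel in WFDB record ", recName)
  fhrIdx <- fhrIdx[1]
  if (sig[[fhrIdx]]$fmt != "16")
    stop("readRecord: unsupported WFDB format ", sig[[fhrIdx]]$fmt)
  dat <- file.path(dirname(hea), sig[[fhrIdx]]$file)
  if (!file.exists(dat)) stop("readRecord: signal file not found: ", dat)
  raw <- readBin(dat, what = "integer", size = 2, endian = "little",
                 n = file.info(dat)$size / 2, signed = TRUE)
  adc <- raw[seq(fhrIdx, length(raw), by = nsig)]
  if (!is.na(nsamp) && length(adc) > nsamp) adc <- adc[seq_len(nsamp)]
  bpm <- (adc - sig[[fhrIdx]]$baseline) / sig[[fhrIdx]]$gain
  meta <- .parseHeaderComments(comments)
  ph <- .findPh(meta)
  FHRRecord(recName, bpm, fs = fs, ph = ph, metadata = meta)
}

#' Write a record in the CSV fixture dialect
#'
#' Inverse of `readRecord(..., dialect = "csv")`: samples are written with
#' full precision so a round trip reproduces them bit-exactly.
#'
#' @param record an [FHRRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecordCSV <- function(record, path) {
  stopifnot(is(record, "FHRRecord"))
  hdr <- c(sprintf("# id=%s", record@recordId),
           sprintf("# fs=%s", format(record@fs, digits = 17)))
  if (!is.na(record@ph))
    hdr <- c(hdr, sprintf("# ph=%s", format(record@ph, digits = 17)))
  if (record@label != "unknown")
    hdr <- c(hdr, sprintf("# label=%s", record@label))
  for (k in names(record@metadata)) {
    v <- record@metadata[[k]]
    if (is.atomic(v) && length(v) == 1)
      hdr <- c(hdr, sprintf("# %s=%s", k, format(v, digits = 17)))
  }
  writeLines(c(hdr, format(record@samples, digits = 17, trim = TRUE,
                           scientific = FALSE)), path)
  invisible(path)
}
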