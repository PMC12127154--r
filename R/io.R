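## Readers and writers for ECG recordings: CSV (samples x leads with header),
## NumPy .npy/.npz dense arrays, and a minimal WFDB subset (.hea + format-16
## .dat). All readers validate finiteness and lead count.

#' Load a multi-lead ECG recording
#'
#' @param path file path: for `csv` a samples-by-leads table with a header row
#'   of lead names; for `npy` a 2-D float array (leads x samples, or samples x
#'   leads with `transpose = TRUE`); for `wfdb` the `.hea` header (or base
#'   name) of a format-16 record pair.
#' @param format one of `"wfdb"`, `"csv"`, `"npy"`.
#' @param fs fallback sampling rate in Hz when the format carries none
#'   (CSV and npy).
#' @param labels optional 0/1 label vector to attach.
#' @param transpose npy only: set `TRUE` if the stored array is samples x leads.
#' @return an [ecg_record()] with signals as leads x samples.
#' @export
load_record <- function(path, format = c("csv", "npy", "wfdb"), fs = 100,
                        labels = NULL, transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path) && format != "wfdb")
    stop("cannot read '", path, "': no such file", call. = FALSE)
  switch(format,
    csv  = read_record_csv(path, fs = fs, labels = labels),
    npy  = {
      m <- read_npy(path)
      if (!is.matrix(m)) stop("npy file '", path, "' is not a 2-D array",
                              call. = FALSE)
      if (isTRUE(transpose)) m <- t(m)
      ecg_record(m, fs = fs, labels = labels,
                 record_id = sub("\\.npy$", "", basename(path)))
    },
    wfdb = read_wfdb(path, labels = labels))
}

#' Read an ECG recording from CSV (samples x leads, header = lead names)
#' @inheritParams load_record
#' @return an [ecg_record()].
#' @export
read_record_csv <- function(path, fs = 100, labels = NULL) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("CSV '", path, "' has ", ncol(df), " lead column(s); need >= 2",
         call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    stop(sprintf("non-numeric cell(s) in column %d ('%s') of '%s'",
                 bad, names(df)[bad], path), call. = FALSE)
  }
  bad <- first_nonfinite(m)
  if (!is.null(bad))
    stop(sprintf("non-finite sample at row %d, column %d of '%s'",
                 bad[1L], bad[2L], path), call. = FALSE)
  ecg_record(t(m), fs = fs, labels = labels,
             record_id = sub("\\.csv$", "", basename(path)),
             lead_names = colnames(df))
}

#' Write an ECG recording to CSV (samples x leads, header = lead names)
#' @param record an [ecg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  m <- t(record$signals)
  colnames(m) <- record$lead_names
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

## ---- NumPy .npy / .npz ------------------------------------------------------

#' Read a NumPy .npy array (float/int, 1-D or 2-D)
#'
#' Supports format versions 1.0/2.0, little-endian `<f8`, `<f4`, `<i8`, `<i4`
#' dtypes, C or Fortran order.
#'
#' @param path path to a `.npy` file, or an open binary connection.
#' @return a numeric vector or matrix.
#' @export
read_npy <- function(path) {
  con <- if (inherits(path, "connection")) path else file(path, "rb")
  if (!inherits(path, "connection")) on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(charToRaw("\x93"), charToRaw("NUMPY"))))
    stop("not a .npy file", call. = FALSE)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1L] >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    stop("unsupported npy dtype '", descr, "'", call. = FALSE))
  vals <- as.numeric(vals)
  if (length(shape) <= 1L) return(vals)    # 0-d scalar or 1-D vector
  if (length(shape) != 2L)
    stop("only 1-D/2-D npy arrays are supported", call. = FALSE)
  if (fortran) matrix(vals, shape[1L], shape[2L])
  else t(matrix(vals, shape[2L], shape[1L]))
}

#' Write a numeric vector or matrix as NumPy .npy (`<f8`, C order)
#' @param x numeric vector or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  shape <- if (is.matrix(x)) sprintf("(%d, %d)", nrow(x), ncol(x))
  else sprintf("(%d,)", length(x))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  total <- 10L + nchar(header) + 1L          # magic+ver+hlen + header + \n
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- if (is.matrix(x)) as.numeric(t(x)) else as.numeric(x)
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an .npz archive with keys "signals", "fs", "labels"
#' @param path path to a `.npz` file (zip of `.npy` members).
#' @return an [ecg_record()].
#' @export
read_npz_record <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  tmp <- tempfile("npz")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- unzip(path, exdir = tmp)
  member <- function(key) {
    hit <- files[basename(files) == paste0(key, ".npy")]
    if (length(hit) != 1L)
      stop("npz archive lacks key '", key, "'", call. = FALSE)
    read_npy(hit)
  }
  sig <- member("signals")
  fs <- as.numeric(member("fs"))[1L]
  labels <- tryCatch(as.numeric(member("labels")), error = function(e) NULL)
  ecg_record(sig, fs = fs, labels = labels,
             record_id = sub("\\.npz$", "", basename(path)))
}

## ---- minimal WFDB (header + format-16 .dat) --------------------------------

#' Read a WFDB record pair (subset: text .hea + format-16 .dat)
#'
#' Parses the record line (`name nsig fs nsamp`) and per-signal lines of the
#' `.hea` header, then reads interleaved int16 little-endian samples from the
#' `.dat` file, converting ADC units to millivolts via each signal's
#' `gain(baseline)` specification.
#'
#' @param path path to the `.hea` file or the record base name.
#' @param labels optional 0/1 label vector to attach.
#' @return an [ecg_record()].
#' @export
read_wfdb <- function(path, labels = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    stop("cannot read '", hea, "': no such file", call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (length(rec_tok) < 4L)
    stop("malformed WFDB record line in '", hea, "'", call. = FALSE)
  nsig <- as.integer(rec_tok[2L])
  fs <- as.numeric(rec_tok[3L])
  nsamp <- as.integer(rec_tok[4L])
  if (nsig < 2L)
    stop("WFDB record has ", nsig, " signal(s); need >= 2", call. = FALSE)
  sig_lines <- lines[2L:(1L + nsig)]
  gains <- numeric(nsig); baselines <- numeric(nsig)
  lead_names <- character(nsig); dat_file <- NULL
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(sig_lines[i]), "\\s+")[[1]]
    dat_file <- tok[1L]
    if (tok[2L] != "16")
      stop("only WFDB format 16 is supported (got '", tok[2L], "')",
           call. = FALSE)
    gb <- tok[3L]                       # gain(baseline)/units
    gains[i] <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gb))
    baselines[i] <- if (grepl("\\(", gb))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gb)) else 0
    lead_names[i] <- if (length(tok) >= 9L) tok[length(tok)] else paste0("L", i)
  }
  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat))
    stop("cannot read '", dat, "': no such file", call. = FALSE)
  adc <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 endian = "little")
  if (length(adc) < nsig * nsamp)
    stop("'", dat, "' is truncated: expected ", nsig * nsamp,
         " samples, got ", length(adc), call. = FALSE)
  m <- matrix(as.numeric(adc), nrow = nsig)   # interleaved by sample
  mv <- (m - baselines) / gains
  ecg_record(mv, fs = fs, labels = labels,
             record_id = rec_tok[1L], lead_names = lead_names)
}

#' Write a WFDB record pair (format 16)
#'
#' @param record an [ecg_record()].
#' @param base output base path (writes `base.hea` and `base.dat`).
#' @param gain ADC gain, units per millivolt.
#' @return `base`, invisibly.
#' @export
write_wfdb <- function(record, base, gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  nsig <- nrow(record$signals); nsamp <- ncol(record$signals)
  adc <- round(record$signals * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds int16 range at gain ", gain, call. = FALSE)
  hea <- c(sprintf("%s %d %g %d", basename(base), nsig, record$fs, nsamp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s", basename(base),
                   gain, record$lead_names))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(base)
}

## ---- label tables ----------------------------------------------------------

#' Read a record-to-classes label table
#'
#' CSV with columns `record_id` and `classes`, the latter a comma-separated
#' list of 1-based class indices (empty = no positive class).
#'
#' @param path CSV path.
#' @param n_classes K, the label-vector length.
#' @return named list of 0/1 vectors keyed by record_id.
#' @export
read_labels_csv <- function(path, n_classes) {
  df <- read.csv(path, colClasses = "character")
  if (!all(c("record_id", "classes") %in% names(df)))
    stop("label table needs columns 'record_id' and 'classes'", call. = FALSE)
  out <- lapply(df$classes, function(s) {
    v <- numeric(n_classes)
    if (nzchar(trimws(s))) {
      idx <- as.integer(strsplit(s, ",")[[1]])
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_classes))
        stop("invalid class index in label table: '", s, "'", call. = FALSE)
      v[idx] <- 1
    }
    v
  })
  setNames(out, df$record_id)
}

#' Write a record-to-classes label table
#' @param labels named list of 0/1 vectors (names = record ids).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(
    record_id = names(labels),
    classes = vapply(labels, function(v) paste(which(v == 1), collapse = ","),
                     character(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
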