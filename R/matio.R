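## Minimal MATLAB level-5 (.mat) I/O for NinaPro-style recordings.
##
## Supports little-endian files containing numeric (and logical/char-free)
## matrices only: uncompressed elements are parsed directly and
## zlib-compressed elements are inflated with memDecompress(). That covers
## the NinaPro DB1/DB2/DB4 field layout (emg, stimulus/restimulus,
## repetition, subject) and files written by scipy.io.savemat. Cell arrays,
## structs, sparse and character data are skipped with a warning.

MI_TYPES <- c(miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L,
              miINT32 = 5L, miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L,
              miINT64 = 12L, miUINT64 = 13L, miMATRIX = 14L,
              miCOMPRESSED = 15L, miUTF8 = 16L)

#' Read numeric variables from a MATLAB v5 `.mat` file
#'
#' @param path Path to the `.mat` file (little-endian level-5 format;
#'   plain or zlib-compressed elements).
#' @return Named list of numeric matrices/arrays.
#' @export
read_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.info(path)$size)
  if (length(raw_all) < 128L) stop("not a MAT v5 file: too short")
  endian <- rawToChar(raw_all[127:128])
  if (endian != "IM") stop("unsupported byte order (expected little-endian 'IM')")
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(raw_all)) {
    tag <- parse_tag(raw_all, pos)
    payload <- raw_all[tag$data_start:(tag$data_start + tag$nbytes - 1L)]
    if (tag$type == MI_TYPES[["miCOMPRESSED"]]) {
      inner <- memDecompress(payload, type = "gzip")
      itag <- parse_tag(inner, 1L)
      if (itag$type == MI_TYPES[["miMATRIX"]]) {
        v <- parse_matrix(inner[itag$data_start:(itag$data_start + itag$nbytes - 1L)])
        if (!is.null(v)) out[[v$name]] <- v$value
      }
    } else if (tag$type == MI_TYPES[["miMATRIX"]]) {
      v <- parse_matrix(payload)
      if (!is.null(v)) out[[v$name]] <- v$value
    }
    pos <- pos + tag$padded
  }
  out
}

parse_tag <- function(raw, pos) {
  w1 <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  small <- bitwAnd(bitwShiftR(w1, 16L), 0xFFFFL)
  if (small != 0L) {  # small data element: 16-bit size, data in bytes 5..8
    list(type = bitwAnd(w1, 0xFFFFL), nbytes = small,
         data_start = pos + 4L, padded = 4L + 4L)
  } else {
    nb <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                  endian = "little")
    list(type = w1, nbytes = nb, data_start = pos + 8L,
         padded = 8L + ceiling(nb / 8) * 8L)
  }
}

read_numeric <- function(raw, type, nbytes) {
  spec <- switch(as.character(type),
    "1" = list("integer", 1L, TRUE), "2" = list("integer", 1L, FALSE),
    "3" = list("integer", 2L, TRUE), "4" = list("integer", 2L, FALSE),
    "5" = list("integer", 4L, TRUE), "6" = list("integer", 4L, FALSE),
    "7" = list("double", 4L, TRUE), "9" = list("double", 8L, TRUE),
    NULL)
  if (is.null(spec)) return(NULL)
  n <- nbytes %/% spec[[2L]]
  as.numeric(readBin(raw, spec[[1L]], n = n, size = spec[[2L]],
                     signed = spec[[3L]], endian = "little"))
}

parse_matrix <- function(raw) {
  pos <- 1L
  tag <- parse_tag(raw, pos)                       # array flags
  flags <- readBin(raw[tag$data_start:(tag$data_start + 3L)], "integer",
                   size = 4L, endian = "little")
  mx_class <- bitwAnd(flags, 0xFFL)
  pos <- pos + tag$padded
  tag <- parse_tag(raw, pos)                       # dimensions
  dims <- readBin(raw[tag$data_start:(tag$data_start + tag$nbytes - 1L)],
                  "integer", n = tag$nbytes %/% 4L, size = 4L, endian = "little")
  pos <- pos + tag$padded
  tag <- parse_tag(raw, pos)                       # name
  nm <- rawToChar(raw[tag$data_start:(tag$data_start + tag$nbytes - 1L)])
  pos <- pos + tag$padded
  if (!mx_class %in% c(6L:15L)) {                  # not a numeric class
    warning("skipping variable '", nm, "' of unsupported class ", mx_class)
    return(NULL)
  }
  tag <- parse_tag(raw, pos)                       # real part
  vals <- read_numeric(raw[tag$data_start:(tag$data_start + tag$nbytes - 1L)],
                       tag$type, tag$nbytes)
  if (is.null(vals)) {
    warning("skipping variable '", nm, "' with unsupported storage type ",
            tag$type)
    return(NULL)
  }
  value <- if (length(dims) == 2L) matrix(vals, dims[1L], dims[2L])
           else array(vals, dims)
  list(name = nm, value = value)
}

#' Write numeric variables to a MATLAB v5 `.mat` file
#'
#' All variables are stored as uncompressed double-precision matrices.
#'
#' @param vars Named list of numeric vectors/matrices/arrays.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by cffemg on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 124L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(as.integer(0x0100), con, size = 2L, endian = "little")
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeBin(mat_element(nm, vars[[nm]]), con)
  invisible(path)
}

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

padded_raw <- function(r) {
  pad <- (8L - length(r) %% 8L) %% 8L
  c(r, raw(pad))
}

mat_element <- function(name, value) {
  value <- as.array(value)
  if (length(dim(value)) == 1L) value <- matrix(value, ncol = 1L)
  dims <- dim(value)
  flags <- c(u32(MI_TYPES[["miUINT32"]]), u32(8L), u32(6L), u32(0L))  # mxDOUBLE
  dim_sub <- c(u32(MI_TYPES[["miINT32"]]), u32(4L * length(dims)),
               unlist(lapply(dims, u32)))
  dim_sub <- padded_raw(dim_sub)
  nm_raw <- charToRaw(name)
  name_sub <- padded_raw(c(u32(MI_TYPES[["miINT8"]]), u32(length(nm_raw)), nm_raw))
  data_raw <- writeBin(as.double(value), raw(), size = 8L, endian = "little")
  data_sub <- padded_raw(c(u32(MI_TYPES[["miDOUBLE"]]), u32(length(data_raw)),
                           data_raw))
  body <- c(flags, dim_sub, name_sub, data_sub)
  c(u32(MI_TYPES[["miMATRIX"]]), u32(length(body)), body)
}

#' Read a NinaPro-style recording from a `.mat` file
#'
#' Expects the DB1/DB2/DB4 field layout: `emg` (`T x C`), a label vector
#' `restimulus` or `stimulus` (`T x 1`; the re-labeled vector is preferred
#' when both are present), a repetition vector `rerepetition` or
#' `repetition`, and optionally a scalar `subject`. Missing fields are
#' reported by name.
#'
#' @param path Path to the `.mat` file.
#' @param fs Sampling rate in Hz (not stored in the files; 100 for DB1,
#'   2000 for DB2/DB4).
#' @return A [raw_recording()].
#' @export
read_ninapro_mat <- function(path, fs) {
  vars <- read_mat(path)
  missing <- character(0)
  if (is.null(vars$emg)) missing <- c(missing, "emg")
  lab <- if (!is.null(vars$restimulus)) vars$restimulus else vars$stimulus
  if (is.null(lab)) missing <- c(missing, "stimulus/restimulus")
  rep_v <- if (!is.null(vars$rerepetition)) vars$rerepetition else vars$repetition
  if (length(missing) > 0L)
    stop("missing field(s) in ", path, ": ", paste(missing, collapse = ", "))
  if (is.null(rep_v)) rep_v <- matrix(0L, nrow(vars$emg), 1L)
  subject <- if (!is.null(vars$subject)) as.integer(vars$subject[1L]) else 1L
  raw_recording(vars$emg, fs, as.integer(lab), as.integer(rep_v), subject)
}

#' Write a recording in the NinaPro field layout
#'
#' @param rec A [raw_recording()].
#' @param path Output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_ninapro_mat <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  write_mat(list(emg = rec$signal,
                 stimulus = matrix(rec$labels, ncol = 1L),
                 repetition = matrix(rec$repetition, ncol = 1L),
                 subject = matrix(as.numeric(rec$subject[1L]), 1L, 1L)),
            path)
}
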