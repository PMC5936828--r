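# Centroided peak lists: a data.frame of (mz, intensity) with spectrum
# metadata (MS level, parent m/z, derivatization, adduct) in attributes.
# I/O as headered CSV with "# key=value" comment lines.

#' Construct a peak list
#'
#' @param mz numeric m/z values (Da), strictly positive; stored sorted.
#' @param intensity non-negative intensities (arbitrary units).
#' @param ms_level 1 or 2.
#' @param parent_mz precursor m/z (required when `ms_level = 2`).
#' @param derivatization derivatization of the analytes.
#' @param adduct adduct label (only `"[M+Na]+"`).
#' @return a data.frame of class `peak_list`, sorted by m/z, with metadata
#'   attributes `ms_level`, `parent_mz`, `derivatization`, `adduct`.
#' @export
peak_list <- function(mz = numeric(), intensity = numeric(), ms_level = 1,
                      parent_mz = NA_real_,
                      derivatization = "permethylated",
                      adduct = "[M+Na]+") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2", call. = FALSE)
  if (ms_level == 2L && is.na(parent_mz))
    stop("ms_level 2 requires parent_mz", call. = FALSE)
  check_adduct(adduct)
  ord <- order(mz)
  structure(
    data.frame(mz = as.numeric(mz)[ord],
               intensity = as.numeric(intensity)[ord]),
    ms_level = as.integer(ms_level), parent_mz = as.numeric(parent_mz),
    derivatization = normalize_derivatization(derivatization),
    adduct = adduct,
    class = c("peak_list", "data.frame"))
}

as_peak_list <- function(x) {
  if (inherits(x, "peak_list")) return(x)
  stopifnot(is.data.frame(x), all(c("mz", "intensity") %in% names(x)))
  peak_list(x$mz, x$intensity,
            ms_level = attr(x, "ms_level") %||% 1L,
            parent_mz = attr(x, "parent_mz") %||% NA_real_,
            derivatization = attr(x, "derivatization") %||% "permethylated")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## rbind a list of data.frame rows; `empty` supplies the zero-row prototype
rbind_rows <- function(rows, empty) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read / write peak lists as commented CSV
#'
#' The on-disk format is a plain CSV with columns `mz,intensity` preceded by
#' `# key=value` comment lines carrying the spectrum metadata
#' (`msLevel`, `parentMz`, `derivatization`, `adduct`).
#'
#' @param path file path.
#' @param peaks a [peak_list()] (for writing).
#' @return `read_peaklist()` returns a [peak_list()];
#'   `write_peaklist()` returns `path` invisibly.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z]+)\\s*=\\s*(.+)\\s*$", h))[[1]]
    if (length(kv) == 3L) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("malformed peak-list CSV ", path, ": need mz,intensity columns",
         call. = FALSE)
  peak_list(df$mz, df$intensity,
            ms_level = as.integer(meta$msLevel %||% 1L),
            parent_mz = as.numeric(meta$parentMz %||% NA_real_),
            derivatization = meta$derivatization %||% "permethylated",
            adduct = meta$adduct %||% "[M+Na]+")
}

#' @rdname read_peaklist
#' @export
write_peaklist <- function(peaks, path) {
  peaks <- as_peak_list(peaks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# msLevel=%d", attr(peaks, "ms_level")),
    if (!is.na(attr(peaks, "parent_mz")))
      sprintf("# parentMz=%.4f", attr(peaks, "parent_mz")),
    sprintf("# derivatization=%s", attr(peaks, "derivatization")),
    sprintf("# adduct=%s", attr(peaks, "adduct"))), con)
  utils::write.csv(as.data.frame(peaks), con, row.names = FALSE)
  invisible(path)
}
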