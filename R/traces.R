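#' Force-extension trace
#'
#' Container for optical-trap time series: time (s), force (pN) and extension
#' (nm) sampled at a fixed acquisition rate.
#'
#' @param time strictly increasing time stamps, s.
#' @param force pN.
#' @param extension nm.
#' @param acquisition_rate Hz.
#' @param metadata free-form named list.
#' @return object of class `fx_trace` (a data.frame with columns `time_s`,
#'   `force_pN`, `extension_nm` and attributes `acquisition_rate`,
#'   `metadata`).
#' @export
fx_trace <- function(time, force, extension, acquisition_rate,
                     metadata = list()) {
  n <- length(time)
  if (length(force) != n || length(extension) != n) {
    stop("time, force and extension must have equal length")
  }
  if (n >= 2 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!is.numeric(acquisition_rate) || acquisition_rate <= 0) {
    stop("acquisition_rate must be positive")
  }
  structure(
    data.frame(time_s = time, force_pN = force, extension_nm = extension),
    acquisition_rate = acquisition_rate,
    metadata = metadata,
    class = c("fx_trace", "data.frame")
  )
}

#' @export
print.fx_trace <- function(x, ...) {
  cat(sprintf(
    "force-extension trace: %d samples at %g Hz, %.2f s, force %.2f..%.2f pN\n",
    nrow(x), attr(x, "acquisition_rate"),
    x$time_s[nrow(x)] - x$time_s[1], min(x$force_pN), max(x$force_pN)
  ))
  invisible(x)
}

#' Magnetic-tweezers twist trace
#'
#' @param time strictly increasing, s.
#' @param extension nm.
#' @param applied_turns magnet turns (scalar or per-sample vector).
#' @param acquisition_rate Hz (default 10).
#' @param metadata free-form named list.
#' @return object of class `twist_trace` (data.frame with columns `time_s`,
#'   `extension_nm`, `applied_turns`).
#' @export
twist_trace <- function(time, extension, applied_turns,
                        acquisition_rate = 10, metadata = list()) {
  n <- length(time)
  if (length(extension) != n) stop("time and extension must have equal length")
  if (n >= 2 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (acquisition_rate <= 0) stop("acquisition_rate must be positive")
  structure(
    data.frame(time_s = time, extension_nm = extension,
               applied_turns = rep_len(applied_turns, n)),
    acquisition_rate = acquisition_rate,
    metadata = metadata,
    class = c("twist_trace", "data.frame")
  )
}

#' @export
print.twist_trace <- function(x, ...) {
  cat(sprintf(
    "twist trace: %d samples at %g Hz, %.0f s, applied turns %g\n",
    nrow(x), attr(x, "acquisition_rate"),
    x$time_s[nrow(x)] - x$time_s[1], x$applied_turns[1]
  ))
  invisible(x)
}

#' Read a trace from a TSV file
#'
#' The canonical interchange format is tab-separated values with a commented
#' header: lines starting `#` hold `key: value` metadata (including
#' `acquisition_rate_hz`), the first non-comment line holds the column names.
#' Stretching/unzipping traces carry `time_s`, `force_pN`, `extension_nm`;
#' twisting traces carry `time_s`, `extension_nm`, `applied_turns`.
#'
#' @param path file path.
#' @param kind `"stretch"` (force-extension) or `"twist"`.
#' @return an [fx_trace()] or [twist_trace()].
#' @export
read_trace <- function(path, kind = c("stretch", "twist")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    if (grepl(":", kv, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", check.names = FALSE)
  rate <- meta[["acquisition_rate_hz"]]
  if (is.null(rate)) {
    if (nrow(tab) < 2) stop("cannot infer acquisition rate")
    rate <- 1 / median(diff(tab$time_s))
  }
  need <- if (kind == "stretch") c("time_s", "force_pN", "extension_nm") else
    c("time_s", "extension_nm", "applied_turns")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  meta[["acquisition_rate_hz"]] <- NULL
  if (kind == "stretch") {
    fx_trace(tab$time_s, tab$force_pN, tab$extension_nm, rate, meta)
  } else {
    twist_trace(tab$time_s, tab$extension_nm, tab$applied_turns, rate, meta)
  }
}

#' Write a trace to a TSV file
#'
#' Inverse of [read_trace()]; metadata and the acquisition rate go into
#' commented header lines.
#'
#' @param trace an [fx_trace()] or [twist_trace()].
#' @param path destination path.
#' @param digits significant digits for the printed values.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path, digits = 10) {
  meta <- attr(trace, "metadata")
  hdr <- c(
    sprintf("# acquisition_rate_hz: %.10g", attr(trace, "acquisition_rate")),
    vapply(names(meta), function(k) {
      sprintf("# %s: %s", k, format(meta[[k]], digits = digits))
    }, character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(trace)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) signif(col, digits) else col
  })
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
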