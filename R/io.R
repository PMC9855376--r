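.TRACESET_FORMAT <- "smbj-traces/1"

#' Write an ensemble of traces to a text container
#'
#' One file per ensemble: `# key=value` header lines carrying acquisition
#' metadata (the first must declare `format=smbj-traces/1`), then one block
#' per trace starting with `TRACE <id> [label=<name>]` followed by
#' tab-separated `distance_nm<TAB>conductance_g0` rows.  Numbers are written
#' with 9 significant digits, so identical inputs yield byte-identical
#' files.
#'
#' @param traces List of [smbj_trace()] objects (may be empty).
#' @param path Output file path.
#' @param metadata Named list of extra `key=value` header entries; values
#'   are coerced with `format()`.  Entries `bias_V`, `sampling_rate_hz` and
#'   `retraction_rate_nm_s` are filled from the first trace when absent.
#' @return `path`, invisibly.
#' @seealso [load_traceset()]
#' @export
write_traceset <- function(traces, path, metadata = list()) {
  if (inherits(traces, "smbj_ensemble")) {
    cfg <- attr(traces, "config")
    defaults <- list(seed = attr(traces, "seed"),
                     beta_decades_nm = cfg$beta, ceiling_g0 = cfg$ceiling,
                     floor_g0 = cfg$floor, noise_sd_decades = cfg$noise_sd,
                     plateau_slope_decades_nm = cfg$plateau_slope)
    for (key in names(defaults)) {
      if (is.null(metadata[[key]])) metadata[[key]] <- defaults[[key]]
    }
  }
  if (length(traces) > 0L) {
    tr1 <- traces[[1]]
    auto <- list(bias_V = tr1$bias, sampling_rate_hz = tr1$sampling_rate,
                 retraction_rate_nm_s = tr1$retraction_rate)
    for (key in names(auto)) {
      if (is.null(metadata[[key]])) metadata[[key]] <- auto[[key]]
    }
  }
  lines <- c(sprintf("# format=%s", .TRACESET_FORMAT),
             vapply(names(metadata), function(key) {
               sprintf("# %s=%s", key,
                       format(metadata[[key]], digits = 9, scientific = NA,
                              trim = TRUE))
             }, character(1)))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    head <- if (is.na(tr$label)) sprintf("TRACE %d", i) else {
      sprintf("TRACE %d label=%s", i, tr$label)
    }
    lines <- c(lines, head,
               sprintf("%.9g\t%.9g", tr$distance, tr$conductance))
  }
  con <- file(path, open = "wb")  # fixed \n endings for byte determinism
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trace container file
#'
#' Parses the format written by [write_traceset()].  Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a `smbj-traces/1` file.
#' @return A list with `traces` (list of [smbj_trace()]) and `metadata`
#'   (named list of header values; numeric where possible).
#' @export
load_traceset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  header <- sub("^#\\s*", "", lines[hdr])
  kv <- strsplit(header, "=", fixed = TRUE)
  metadata <- list()
  for (pair in kv) {
    if (length(pair) != 2L) next
    val <- trimws(pair[2])
    num <- suppressWarnings(as.numeric(val))
    metadata[[trimws(pair[1])]] <- if (is.na(num)) val else num
  }
  if (!identical(metadata$format, .TRACESET_FORMAT)) {
    stop("unknown or missing trace format version (need format=",
         .TRACESET_FORMAT, ")", call. = FALSE)
  }
  bias <- metadata$bias_V %||% NA_real_
  fs <- metadata$sampling_rate_hz %||% NA_real_
  vr <- metadata$retraction_rate_nm_s %||% NA_real_

  starts <- grep("^TRACE\\b", lines)
  traces <- vector("list", length(starts))
  ends <- c(starts[-1] - 1L, length(lines))
  for (j in seq_along(starts)) {
    head <- lines[starts[j]]
    label <- if (grepl("label=", head, fixed = TRUE)) {
      sub(".*label=", "", head)
    } else NA_character_
    body_idx <- setdiff(seq(starts[j] + 1L, length.out = max(ends[j] - starts[j], 0L)),
                        hdr)
    body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
    if (length(body_idx) < 1L) {
      stop(sprintf("line %d: trace block with no samples", starts[j]),
           call. = FALSE)
    }
    parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad)) {
      stop(sprintf("line %d: expected two tab-separated columns",
                   body_idx[bad[1]]), call. = FALSE)
    }
    m <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
    if (anyNA(m)) {
      bad_row <- which(apply(is.na(m), 1, any))[1]
      stop(sprintf("line %d: non-numeric sample row", body_idx[bad_row]),
           call. = FALSE)
    }
    traces[[j]] <- smbj_trace(distance = m[, 1], conductance = m[, 2],
                              bias = bias, sampling_rate = fs,
                              retraction_rate = vr, label = label)
  }
  list(traces = traces, metadata = metadata)
}

#' Write a histogram to a two-column text file
#'
#' @param hist An [build_histogram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  lines <- c("# format=smbj-histogram/1",
             sprintf("# n_traces=%d", hist$n_traces),
             "# bin_center_log10_g0\tcounts",
             sprintf("%.9g\t%d", hist$centers, hist$counts))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a sectioned key=value configuration file
#'
#' Flat INI-style text: `[section]` headers with `key = value` lines;
#' blank lines and `#` comments are ignored.  Values are parsed as numbers
#' where possible; comma-separated values become vectors.
#'
#' @param path Path to the config file.
#' @return Nested named list, one element per section.
#' @seealso [smbj_config()] for validation.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  cfg <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      cfg[[section]] <- cfg[[section]] %||% list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stop(sprintf("line %d: expected key = value", i), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    parsed <- if (anyNA(nums)) parts else nums
    if (is.null(section)) {
      cfg[[key]] <- parsed
    } else {
      cfg[[section]][[key]] <- parsed
    }
  }
  cfg
}
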