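#' Write a series to a plain-text file
#'
#' Two dialects: `"plain"` — one sample per line, optionally followed by
#' the label in a second whitespace-separated column; `"csv"` — header
#' `n,phi` or `n,phi,label` with 1-based `n`.  Floats are rendered with 17
#' significant digits so that a write–read round trip reproduces them
#' exactly.
#'
#' @param x A `spike_train` or a numeric vector.
#' @param path Output file path.
#' @param dialect `"plain"` or `"csv"`.
#' @param labels Include the label column (only meaningful for spike
#'   trains; default `TRUE` for `"csv"`, `FALSE` for `"plain"`).
#' @return `path`, invisibly.
#' @seealso [read_series()]
#' @export
write_series <- function(x, path, dialect = c("plain", "csv"),
                         labels = NULL) {
  dialect <- match.arg(dialect)
  is_st <- inherits(x, "spike_train")
  samples <- if (is_st) x$samples else x
  stopifnot(is.numeric(samples))
  if (is.null(labels)) labels <- is_st && dialect == "csv"
  if (labels && !is_st)
    stop("labels requested but 'x' carries none")
  num <- sprintf("%.17g", samples)
  lines <- if (dialect == "plain") {
    if (labels) paste(num, as.character(x$labels)) else num
  } else {
    if (labels)
      c("n,phi,label",
        paste(seq_along(samples), num, as.character(x$labels), sep = ","))
    else
      c("n,phi", paste(seq_along(samples), num, sep = ","))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a series written by [write_series()]
#'
#' Auto-detects the dialect from the header line when not given.  Malformed
#' numeric fields raise a parse error naming the offending line.
#'
#' @param path Input file path.
#' @param dialect `"plain"`, `"csv"`, or `NULL` to auto-detect.
#' @return A numeric vector of samples; if a label column is present it is
#'   attached as attribute `"labels"` (character, same length).
#' @export
read_series <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty series file: '%s'", path))
  if (is.null(dialect))
    dialect <- if (grepl("^n,phi(,label)?$", trimws(lines[1]))) "csv" else "plain"
  parse_num <- function(tok, lineno) {
    v <- suppressWarnings(as.numeric(tok))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error at line %d of '%s': '%s' is not a number",
                   lineno[bad[1]], path, tok[bad[1]]))
    v
  }
  if (dialect == "csv") {
    header <- strsplit(trimws(lines[1]), ",")[[1]]
    if (!identical(header[1:2], c("n", "phi")))
      stop(sprintf("parse error at line 1 of '%s': expected 'n,phi[,label]' header",
                   path))
    body <- lines[-1]
    parts <- strsplit(body, ",")
    nf <- lengths(parts)
    if (any(nf != length(header)))
      stop(sprintf("parse error at line %d of '%s': expected %d fields",
                   which(nf != length(header))[1] + 1L, path, length(header)))
    m <- do.call(rbind, parts)
    samples <- parse_num(m[, 2], seq_along(body) + 1L)
    if (ncol(m) >= 3) attr(samples, "labels") <- m[, 3]
    samples
  } else {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    nf <- lengths(parts)
    samples <- parse_num(vapply(parts, `[`, "", 1L), seq_along(lines))
    if (all(nf >= 2))
      attr(samples, "labels") <- vapply(parts, `[`, "", 2L)
    samples
  }
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Recognized keys: `z1, u1, eps1, z2, u2, eps2, th1, th2, phi_k, phi_m,
#' phi_init, n_samples, seed, entry_mode`.
#'
#' @param path Config file path.
#' @return Named list of values (numeric where possible).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- c("z1", "u1", "eps1", "z2", "u2", "eps2", "th1", "th2",
             "phi_k", "phi_m", "phi_init", "n_samples", "seed", "entry_mode")
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE))
      stop(sprintf("config parse error at '%s': expected key = value", lines[i]))
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% known)
      stop(sprintf("unknown config key '%s'", key))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (key == "entry_mode" || is.na(num)) val else num
  }
  out
}
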