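#' Assigned 2D (1H,15N) peak lists
#'
#' A `peaklist` is a data frame of assigned amide cross peaks, one row per
#' peak, with columns `chain` (single character), `seqnum` (author residue
#' number), `aa` (one-letter code, `"X"` if unknown), `shift_h` (1H shift,
#' ppm), `shift_n` (15N shift, ppm), `intensity` (arbitrary units, >= 0) and
#' `state` (`"A"`, `"B"` or `"unknown"`). Doubled spectra carry two rows per
#' residue, one per conformational state.
#'
#' @param peaks data frame with the columns above (`state` optional,
#'   defaulting to `"unknown"`).
#' @param source provenance string recorded as an attribute.
#' @return A `peaklist` object (data frame subclass).
#' @examples
#' pl <- peaklist(data.frame(chain = "A", seqnum = 283, aa = "V",
#'                           shift_h = 8.1, shift_n = 121.5,
#'                           intensity = 1, state = "A"))
#' @export
peaklist <- function(peaks, source = "r") {
  if (!is.data.frame(peaks)) stop_ad("`peaks` must be a data frame")
  need <- c("chain", "seqnum", "aa", "shift_h", "shift_n", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop_ad("peak list missing columns: ",
                            paste(miss, collapse = ", "))
  if (is.null(peaks$state)) peaks$state <- "unknown"
  peaks <- peaks[c(need, "state")]
  peaks$chain <- as.character(peaks$chain)
  peaks$aa <- toupper(as.character(peaks$aa))
  peaks$state <- as.character(peaks$state)
  if (nrow(peaks)) {
    validate_peak_fields(peaks)
    key <- with(peaks, paste(chain, seqnum, state, shift_h, shift_n))
    if (anyDuplicated(key))
      stop_ad("duplicate peaks (same residue, state and shifts)")
  }
  structure(peaks, source = source,
            class = c("peaklist", "data.frame"))
}

validate_peak_fields <- function(peaks) {
  bad_aa <- !(peaks$aa %in% c(AA1, "X"))
  if (any(bad_aa))
    stop_ad("invalid amino-acid code(s): ",
            paste(unique(peaks$aa[bad_aa]), collapse = ", "))
  if (!all(peaks$state %in% c("A", "B", "unknown")))
    stop_ad("state must be one of 'A', 'B', 'unknown'")
  if (any(!is.finite(peaks$shift_h)) || any(peaks$shift_h < 0 | peaks$shift_h > 14))
    stop_ad("shift_h out of the amide window [0, 14] ppm")
  if (any(!is.finite(peaks$shift_n)) || any(peaks$shift_n < 95 | peaks$shift_n > 140))
    stop_ad("shift_n out of the amide window [95, 140] ppm")
  if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0))
    stop_ad("intensity must be finite and >= 0")
  invisible(TRUE)
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("peaklist: %d peaks, %d residues (source: %s)\n",
              nrow(x), length(unique(x$seqnum)),
              attr(x, "source") %||% "?"))
  NextMethod()
}

#' Read an assigned peak list
#'
#' Two dialects are supported. `"tsv"` is a tab-separated table with a
#' mandatory header `residue chain aa dH dN intensity state` (`state`
#' optional; `"?"` means unknown). `"sparky"` is a Sparky-style list with
#' columns `Assignment w1 w2 Height`, where w1 is the 15N shift and w2 the
#' 1H shift, and assignments look like `V283N-H`; a lowercase `a`/`b`
#' immediately after the residue number carries the state label
#' (e.g. `V283aN-H`). Sparky lists carry no chain; chain defaults to
#' `default_chain`.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"sparky"`.
#' @param default_chain chain label assumed by the sparky dialect.
#' @return A [peaklist].
#' @export
read_peaklist <- function(path, dialect = c("tsv", "sparky"),
                          default_chain = "A") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ad("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) {
    warn_ad("empty peak list: ", path)
    return(peaklist(data.frame(chain = character(), seqnum = integer(),
                               aa = character(), shift_h = numeric(),
                               shift_n = numeric(), intensity = numeric(),
                               state = character()), source = path))
  }
  if (dialect == "tsv") read_peaklist_tsv(lines, path)
  else read_peaklist_sparky(lines, path, default_chain)
}

read_peaklist_tsv <- function(lines, path) {
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("residue", "chain", "aa", "dH", "dN", "intensity")
  if (!all(need %in% header))
    stop_ad("tsv peak list header must contain: ",
            paste(need, collapse = ", "))
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < length(header))
      stop_ad("line ", i, ": expected ", length(header), " fields, got ",
              length(f))
    stats::setNames(as.list(f[seq_along(header)]), header)
  })
  num <- function(field, i, what) {
    v <- suppressWarnings(as.numeric(field))
    if (is.na(v)) stop_ad("line ", i + 1L, ": cannot parse ", what,
                          " value '", field, "'")
    v
  }
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(chain = r$chain,
               seqnum = as.integer(num(r$residue, i, "residue")),
               aa = r$aa,
               shift_h = num(r$dH, i, "dH"),
               shift_n = num(r$dN, i, "dN"),
               intensity = num(r$intensity, i, "intensity"),
               state = if (is.null(r$state) || r$state == "?") "unknown"
                       else r$state)
  }))
  peaklist(df, source = path)
}

read_peaklist_sparky <- function(lines, path, default_chain) {
  if (grepl("^\\s*Assignment", lines[[1]])) lines <- lines[-1]
  rx <- "^([A-Z])(\\d+)([ab]?)N-H$"
  df <- do.call(rbind, lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 4)
      stop_ad("line ", i, ": expected 'Assignment w1 w2 Height'")
    if (!grepl(rx, f[1]))
      stop_ad("line ", i, ": cannot parse assignment '", f[1], "'")
    w <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(w)) stop_ad("line ", i, ": non-numeric shift or height")
    st <- sub(rx, "\\3", f[1])
    data.frame(chain = default_chain,
               seqnum = as.integer(sub(rx, "\\2", f[1])),
               aa = sub(rx, "\\1", f[1]),
               shift_h = w[2], shift_n = w[1], intensity = w[3],
               state = c(a = "A", b = "B")[st] %||% "unknown")
  }))
  df$state[is.na(df$state)] <- "unknown"
  peaklist(df, source = path)
}

#' Write an assigned peak list
#'
#' Inverse of [read_peaklist()]; `read(write(x))` reproduces `x` up to float
#' formatting. Unknown states are written as `"?"` (tsv) or as a bare
#' assignment with no state letter (sparky).
#'
#' @param peaks a [peaklist].
#' @param path output file.
#' @param dialect `"tsv"` or `"sparky"`.
#' @export
write_peaklist <- function(peaks, path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- data.frame(residue = peaks$seqnum, chain = peaks$chain,
                     aa = peaks$aa,
                     dH = sprintf("%.6f", peaks$shift_h),
                     dN = sprintf("%.6f", peaks$shift_n),
                     intensity = sprintf("%.6g", peaks$intensity),
                     state = ifelse(peaks$state == "unknown", "?",
                                    peaks$state))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df))
      writeLines(do.call(paste, c(df, sep = "\t")), con)
  } else {
    st <- c(A = "a", B = "b", unknown = "")[peaks$state]
    lines <- sprintf("%s%d%sN-H %10.4f %10.4f %14.6g",
                     peaks$aa, peaks$seqnum, st,
                     peaks$shift_n, peaks$shift_h, peaks$intensity)
    writeLines(c("Assignment        w1        w2         Height", lines),
               path)
  }
  invisible(path)
}
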