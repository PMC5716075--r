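#' Sequence records with author numbering
#'
#' A `seqrec` couples a one-letter protein sequence to the author residue
#' numbering of the construct it represents: string position 1 corresponds
#' to author residue `offset` (e.g. 239 for the PACT construct spanning
#' residues 239-313).
#'
#' @param id record identifier.
#' @param residues one-letter sequence (uppercase; `X` allowed).
#' @param offset author residue number of the first position.
#' @return A `seqrec` object.
#' @export
seqrec <- function(id, residues, offset = 1L) {
  residues <- toupper(as.character(residues))
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(chars, c(AA1, "X"))
  if (length(bad)) stop_ad("invalid residue letter(s) in '", id, "': ",
                           paste(unique(bad), collapse = ", "))
  stopifnot(is_number(offset))
  structure(list(id = as.character(id), residues = residues,
                 offset = as.integer(offset)),
            class = "seqrec")
}

#' @export
print.seqrec <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("seqrec %s: %d aa, residues %d-%d\n", x$id, n, x$offset,
              x$offset + n - 1L))
  invisible(x)
}

#' Author residue numbers covered by a record
#' @param rec a [seqrec].
#' @export
seq_positions <- function(rec) {
  seq.int(rec$offset, length.out = nchar(rec$residues))
}

#' Read a FASTA file
#'
#' Gap characters are stripped with a warning and lowercase letters are
#' uppercased. Each record gets `numbering_offset` 1 unless an entry in
#' `offsets` (named by record id) says otherwise.
#'
#' @param path FASTA file.
#' @param offsets optional named integer vector of author numbering offsets.
#' @return List of [seqrec] objects.
#' @export
read_fasta <- function(path, offsets = NULL) {
  if (!file.exists(path)) stop_ad("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) return(list())
  if (!startsWith(lines[[1]], ">"))
    stop_ad("sequence line before first FASTA header")
  idx <- cumsum(startsWith(lines, ">"))
  recs <- split(lines, idx)
  out <- lapply(recs, function(block) {
    id <- sub("^>\\s*", "", block[[1]])
    id <- strsplit(id, "\\s+")[[1]][1]
    seqtxt <- paste(block[-1], collapse = "")
    if (grepl("[-.]", seqtxt)) {
      warn_ad("gaps stripped from FASTA record '", id, "'")
      seqtxt <- gsub("[-.]", "", seqtxt)
    }
    if (!nchar(seqtxt))
      warn_ad("empty sequence under FASTA header '", id, "'")
    seqrec(id, toupper(seqtxt), offset = offsets[[id]] %||% 1L)
  })
  unname(out)
}

#' Percent sequence identity over pre-aligned positions
#'
#' Compares two already position-aligned sequences residue by residue over
#' the author residue numbers both records share (or over an explicit
#' `positions` mask, e.g. an interface residue set) and reports
#' `100 * matches / compared`. No alignment is performed.
#'
#' @param a,b [seqrec] objects.
#' @param positions optional author residue numbers to restrict the
#'   comparison to; every position must map into both sequences.
#' @return List with `percent`, `n_compared` and the compared `positions`.
#' @export
percent_identity <- function(a, b, positions = NULL) {
  pa <- seq_positions(a)
  pb <- seq_positions(b)
  shared <- intersect(pa, pb)
  if (is.null(positions)) positions <- shared
  positions <- sort(unique(as.integer(positions)))
  if (!all(positions %in% pa) || !all(positions %in% pb))
    stop_ad("positions outside one of the sequences: ",
            paste(setdiff(positions, shared), collapse = ", "))
  if (!length(positions)) stop_ad("zero compared positions")
  ca <- strsplit(a$residues, "")[[1]][match(positions, pa)]
  cb <- strsplit(b$residues, "")[[1]][match(positions, pb)]
  list(percent = 100 * mean(ca == cb),
       n_compared = length(positions),
       positions = positions)
}
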