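# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the RNG alone.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is_number(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Most frequent value; ties broken by the smaller value.
#' @noRd
modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")

AA123 <- stats::setNames(names(AA321), unname(AA321))

#' @noRd
stop_ad <- function(...) stop(..., call. = FALSE)

#' @noRd
warn_ad <- function(...) warning(..., call. = FALSE)
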