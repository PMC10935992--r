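# IUPAC nucleotide one-letter codes (incl. U); the default alphabet for
# collections read from FASTA.  '$' and '#' are sentinels, never part of it.
IUPAC_CODES <- c("A", "B", "C", "D", "G", "H", "K", "M", "N",
                 "R", "S", "T", "U", "V", "W", "Y")

# Sentinel conventions used throughout: every collection document ends in '$',
# the reference ends in '#', and '#' < '$' < every alphabet symbol.
COLLECTION_SENTINEL <- "$"
REFERENCE_SENTINEL  <- "#"

#' Build a string collection
#'
#' Wraps a character vector of documents into a validated collection object.
#' Each document is upper-cased and terminated with the collection sentinel
#' \code{"$"}, which is smaller than every alphabet symbol (and larger only
#' than the reference sentinel \code{"#"}).
#'
#' @param x character vector of sequences (one document each).  A trailing
#'   \code{"$"} is appended when absent; \code{"$"} must not occur elsewhere.
#' @param alphabet allowed symbols (default: IUPAC nucleotide codes).
#' @return an object of class \code{string_collection} with fields
#'   \code{docs} (documents including their sentinel), \code{m} (number of
#'   documents) and \code{N} (total length including sentinels).
#' @examples
#' cc <- string_collection(c("GATTACA", "GATTACA"))
#' cc$m
#' cc$N
#' @export
string_collection <- function(x, alphabet = IUPAC_CODES) {
  if (length(x) < 1L) stop("collection must contain at least one document")
  x <- toupper(as.character(x))
  x <- ifelse(endsWith(x, COLLECTION_SENTINEL), x,
              paste0(x, COLLECTION_SENTINEL))
  for (d in seq_along(x)) {
    body <- substr(x[d], 1L, nchar(x[d]) - 1L)
    if (nchar(body) == 0L) stop("document ", d, " is empty")
    syms <- unique(strsplit(body, "", fixed = TRUE)[[1L]])
    bad <- setdiff(syms, alphabet)
    if (length(bad) > 0L) {
      stop("document ", d, " contains symbol(s) outside the alphabet: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(docs = x, m = length(x),
                 N = sum(nchar(x))),
            class = "string_collection")
}

#' @export
print.string_collection <- function(x, ...) {
  cat("String collection: m =", x$m, "documents, N =", x$N,
      "total symbols (incl. '$' sentinels)\n")
  show <- utils::head(x$docs, 3L)
  for (d in seq_along(show)) {
    s <- show[d]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  S_%d: %s\n", d, s))
  }
  if (x$m > 3L) cat("  ...\n")
  invisible(x)
}

# Full symbol order for an analysis: '#' < '$' < alphabet symbols in their
# natural (ASCII) order.  Ranks are the 1-based positions in this vector.
symbol_order <- function(collection, ref = NULL) {
  syms <- unique(unlist(strsplit(collection$docs, "", fixed = TRUE)))
  if (!is.null(ref)) syms <- union(syms, strsplit(ref, "", fixed = TRUE)[[1L]])
  syms <- setdiff(syms, c(COLLECTION_SENTINEL, REFERENCE_SENTINEL))
  c(REFERENCE_SENTINEL, COLLECTION_SENTINEL, sort(syms, method = "radix"))
}

# Encode a string as 1-based integer ranks under `alph` (ASCII only).
encode_symbols <- function(x, alph) {
  map <- integer(128L)
  map[vapply(alph, utf8ToInt, 0L)] <- seq_along(alph)
  code <- map[utf8ToInt(x)]
  if (any(code == 0L)) {
    bad <- intToUtf8(utf8ToInt(x)[code == 0L][1L])
    stop("symbol '", bad, "' is not in the analysis alphabet")
  }
  code
}

decode_symbols <- function(code, alph) {
  paste(alph[code], collapse = "")
}
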