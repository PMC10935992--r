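# FASTA input, GSA output, synthetic-collection generation and the
# brute-force oracles used throughout testing.

#' Read a multi-FASTA file as a string collection
#'
#' Records become documents in file order; sequences are upper-cased,
#' validated against the alphabet and terminated with \code{"$"}.  Duplicate
#' headers are tolerated; gzip input is handled transparently.
#'
#' @param path FASTA file.
#' @param alphabet allowed symbols (default IUPAC nucleotide codes).
#' @return a \code{\link{string_collection}}.
#' @export
read_fasta_collection <- function(path, alphabet = IUPAC_CODES) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("no FASTA records in ", path,
                                            " (", conditionMessage(e), ")"))
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  string_collection(as.character(recs), alphabet = alphabet)
}

#' Read the first FASTA record as a reference string
#'
#' @param path FASTA file.
#' @return bare sequence string (no sentinel).
#' @export
read_fasta_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  toupper(as.character(recs[[1L]]))
}

GSA_MAGIC <- c(charToRaw("GSAMS"), as.raw(c(1L, 0L, 0L)))  # name + version

#' Write a GSA to disk
#'
#' Text mode writes TSV lines \code{rank, d, j} (all 1-based, with a header
#' row); binary mode writes an 8-byte magic/version header followed by
#' little-endian 32-bit \code{(d, j)} pairs.  Both round-trip losslessly
#' through \code{\link{read_gsa}}.
#'
#' @param gsa a \code{gsa} object or an integer matrix with columns
#'   \code{d}, \code{j}.
#' @param path output file.
#' @param mode \code{"text"} or \code{"binary"}.
#' @export
write_gsa <- function(gsa, path, mode = c("text", "binary")) {
  mode <- match.arg(mode)
  g <- if (inherits(gsa, "gsa")) gsa$gsa else as.matrix(gsa)
  if (nrow(g) == 0L) stop("refusing to write an empty GSA")
  if (mode == "text") {
    df <- data.frame(rank = seq_len(nrow(g)), d = g[, 1L], j = g[, 2L])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(GSA_MAGIC, con)
    writeBin(as.integer(t(g)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a GSA written by \code{\link{write_gsa}}
#'
#' The mode is auto-detected from the magic header.
#'
#' @param path file written by \code{\link{write_gsa}}.
#' @return integer matrix with columns \code{d}, \code{j}.
#' @export
read_gsa <- function(path) {
  con <- file(path, "rb")
  head8 <- readBin(con, "raw", 8L)
  if (identical(head8, GSA_MAGIC)) {
    sz <- file.info(path)$size - 8L
    v <- readBin(con, "integer", n = sz %/% 4L, size = 4L, endian = "little")
    close(con)
    g <- matrix(v, ncol = 2L, byrow = TRUE)
  } else {
    close(con)
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    g <- cbind(df$d, df$j)
  }
  dimnames(g) <- list(NULL, c("d", "j"))
  g
}

#' Generate a synthetic collection of mutated reference copies
#'
#' Draws a uniform random A/C/G/T reference of the requested length, then
#' produces \code{m} copies, each mutated at \code{floor(rate * ref_len)}
#' distinct uniformly chosen positions by substituting a character drawn
#' uniformly from the three other nucleotides (never the original).
#' Deterministic under \code{seed}.  This emulates collections of similar
#' genomes whose divergence from the reference is controlled by the
#' substitution rate.
#'
#' @param ref_len reference length.
#' @param m number of mutated copies.
#' @param rate substitution rate in \code{[0, 1]}.
#' @param seed RNG seed.
#' @return list with \code{reference} (bare string) and \code{collection}
#'   (a \code{\link{string_collection}} of the m copies).
#' @examples
#' g <- generate_collection(100, 3, 0.05, seed = 1)
#' g$collection$m
#' @export
generate_collection <- function(ref_len, m, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  if (ref_len < 1L || m < 1L) stop("`ref_len` and `m` must be positive")
  nuc <- c("A", "C", "G", "T")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ref <- sample(nuc, ref_len, replace = TRUE)
  k <- floor(rate * ref_len)
  docs <- vapply(seq_len(m), function(d) {
    s <- ref
    if (k > 0L) {
      pos <- sample.int(ref_len, k)
      s[pos] <- vapply(s[pos],
                       function(b) sample(setdiff(nuc, b), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  list(reference = paste(ref, collapse = ""),
       collection = string_collection(docs))
}

#' Brute-force generalized suffix array
#'
#' Sorts every \code{(d, j)} coordinate by its suffix string (C-locale radix
#' order, under which \code{"#" < "$" <} letters), ties broken by document
#' index.  The reference oracle for every end-to-end test; quadratic in
#' memory, so only for test-scale inputs.
#'
#' @param collection a \code{\link{string_collection}}.
#' @return integer matrix with columns \code{d}, \code{j}.
#' @export
naive_gsa <- function(collection) {
  lens <- nchar(collection$docs)
  d <- rep(seq_len(collection$m), times = lens)
  j <- unlist(lapply(lens, seq_len))
  suf <- substring(collection$docs[d], j)
  o <- order(suf, d, method = "radix")
  cbind(d = d[o], j = j[o])
}

#' Brute-force matching statistics
#'
#' For every position of \code{s}, finds the longest prefix of the suffix
#' occurring anywhere in \code{ref} by direct substring search (leftmost
#' occurrence reported).  Independent of the index-based computation; used
#' as its oracle.
#'
#' @param s document string (a \code{"$"} is appended if absent).
#' @param ref reference string (a \code{"#"} is appended if absent).
#' @return data.frame with columns \code{i}, \code{p}, \code{ell}.
#' @export
naive_ms <- function(s, ref) {
  if (!endsWith(s, COLLECTION_SENTINEL)) s <- paste0(s, COLLECTION_SENTINEL)
  if (!endsWith(ref, REFERENCE_SENTINEL)) ref <- paste0(ref, REFERENCE_SENTINEL)
  n <- nchar(s)
  p <- integer(n); ell <- integer(n)
  for (i in seq_len(n)) {
    l <- 0L
    repeat {
      if (i + l > n) break
      cand <- substr(s, i, i + l)
      if (!grepl(cand, ref, fixed = TRUE)) break
      l <- l + 1L
    }
    ell[i] <- l
    p[i] <- if (l == 0L) -1L else regexpr(substr(s, i, i + l - 1L), ref,
                                          fixed = TRUE)[1L]
  }
  data.frame(i = seq_len(n), p = p, ell = ell)
}
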