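# Reference-side structures: augmented reference, SA, ISA, LCP, blockwise
# LCP maxima, and threshold PSV/NSV queries.

#' Augment a reference with missing symbol runs
#'
#' Every symbol occurring in the collection must occur in the reference for
#' the matching statistics (and in particular the insert point) to be well
#' defined.  For each collection symbol absent from the reference, a run of
#' that symbol — as long as the longest run of it anywhere in the collection —
#' is inserted immediately before the terminal \code{"#"}, which stays last
#' and smallest.
#'
#' @param ref reference string ending in \code{"#"}.
#' @param collection a \code{\link{string_collection}}.
#' @return list with \code{ref} (augmented string), \code{orig_len} (length
#'   before augmentation, including \code{"#"}) and \code{runs} (named
#'   integer vector of inserted run lengths; empty when nothing was missing).
#' @examples
#' cc <- string_collection("ANNC")
#' augment_reference("AC#", cc)$ref
#' @export
augment_reference <- function(ref, collection) {
  if (!endsWith(ref, REFERENCE_SENTINEL)) {
    stop("reference must end in '", REFERENCE_SENTINEL, "'")
  }
  if (!inherits(collection, "string_collection")) {
    stop("`collection` must be a string_collection")
  }
  orig_len <- nchar(ref)
  ref_syms <- unique(strsplit(ref, "", fixed = TRUE)[[1L]])
  coll_syms <- setdiff(
    unique(unlist(strsplit(collection$docs, "", fixed = TRUE))),
    COLLECTION_SENTINEL)
  missing <- sort(setdiff(coll_syms, ref_syms), method = "radix")
  runs <- integer(0L)
  if (length(missing) > 0L) {
    runs <- vapply(missing, function(s) {
      max(vapply(collection$docs, function(doc) {
        r <- rle(strsplit(doc, "", fixed = TRUE)[[1L]])
        len <- r$lengths[r$values == s]
        if (length(len)) max(len) else 0L
      }, 0L))
    }, 0L)
    body <- substr(ref, 1L, orig_len - 1L)
    ref <- paste0(body,
                  paste(rep(missing, times = runs), collapse = ""),
                  REFERENCE_SENTINEL)
  }
  list(ref = ref, orig_len = orig_len, runs = runs)
}

# Manber-Myers prefix doubling on an integer vector; O(n log n) with all
# heavy lifting inside order()/cumsum().  No sentinel requirement: a suffix
# that is a proper prefix of another sorts first (virtual past-end rank 0).
suffix_array_int <- function(x) {
  n <- length(x)
  if (n == 0L) stop("cannot suffix-sort an empty sequence")
  if (n == 1L) return(1L)
  rk <- match(x, sort(unique(x)))
  k <- 1L
  repeat {
    r2 <- c(rk[-seq_len(k)], integer(min(k, n)))  # rank at offset k, 0 past end
    o <- order(rk, r2, method = "radix")
    new_group <- c(TRUE, rk[o[-1L]] != rk[o[-n]] | r2[o[-1L]] != r2[o[-n]])
    nr <- integer(n)
    nr[o] <- cumsum(new_group)
    rk <- nr
    if (rk[o[n]] == n) return(o)
    k <- k * 2L
  }
}

#' Build the suffix array of a sentinel-terminated string
#'
#' Self-contained prefix-doubling construction: the permutation \code{SA}
#' with \code{SA[i] = j} when the j-th suffix is i-th in lexicographic order.
#'
#' @param x a single string whose last character is a sentinel (\code{"#"} or
#'   \code{"$"}) occurring nowhere else, or an integer vector (arbitrary
#'   integer alphabet, no sentinel requirement).
#' @return integer permutation of \code{1..nchar(x)}.
#' @examples
#' build_suffix_array("A#")
#' @export
build_suffix_array <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L || nchar(x) == 0L) stop("need one non-empty string")
    last <- substr(x, nchar(x), nchar(x))
    if (!last %in% c(REFERENCE_SENTINEL, COLLECTION_SENTINEL)) {
      stop("input must be terminated by a sentinel ('#' or '$')")
    }
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (sum(chars == last) != 1L) {
      stop("sentinel '", last, "' must occur exactly once, at the end")
    }
    x <- match(chars, sort(unique(chars), method = "radix"))
  }
  if (!is.numeric(x)) stop("input must be a string or an integer vector")
  suffix_array_int(as.integer(x))
}

#' Invert a suffix array
#'
#' @param sa integer permutation of \code{1..n}.
#' @return the inverse permutation \code{ISA} with \code{ISA[SA[i]] = i}.
#' @export
build_inverse <- function(sa) {
  n <- length(sa)
  if (n == 0L || !setequal(sa, seq_len(n))) {
    stop("`sa` must be a permutation of 1..n")
  }
  isa <- integer(n)
  isa[sa] <- seq_len(n)
  isa
}

#' Build the LCP array (Kasai's algorithm)
#'
#' \code{LCP[1] = 0}; for \code{i >= 2}, \code{LCP[i]} is the length of the
#' longest common prefix of the lexicographically adjacent suffixes
#' \code{x[SA[i-1]..]} and \code{x[SA[i]..]}.
#'
#' @param x string or integer vector (same input as
#'   \code{\link{build_suffix_array}}, validation relaxed for vectors).
#' @param sa its suffix array.
#' @return integer LCP array of the same length.
#' @export
build_lcp <- function(x, sa) {
  if (is.character(x)) {
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    x <- match(chars, sort(unique(chars), method = "radix"))
  }
  x <- as.integer(x)
  n <- length(x)
  if (length(sa) != n) stop("`sa` length does not match the sequence")
  isa <- build_inverse(sa)
  lcp <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    r <- isa[i]
    if (r > 1L) {
      j <- sa[r - 1L]
      while (i + h <= n && j + h <= n && x[i + h] == x[j + h]) h <- h + 1L
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Blockwise maxima of an LCP array
#'
#' Divides the array into blocks of size \code{b} (the last block may be
#' short) and records the maximum of each block.  Used by the leaf-branch
#' fast path of the matching-statistics computation: a small array of maxima
#' stands in for random accesses to the full LCP array.
#'
#' @param lcp integer array.
#' @param b block size, \code{b >= 1}.
#' @return integer vector of length \code{ceiling(length(lcp)/b)}.
#' @export
build_block_max <- function(lcp, b) {
  if (b < 1L) stop("block size must be >= 1")
  n <- length(lcp)
  grp <- (seq_len(n) - 1L) %/% as.integer(b) + 1L
  as.integer(tapply(lcp, grp, max))
}

#' Threshold previous-smaller-value query
#'
#' \code{psv_threshold(A, i, t)} returns the greatest \code{i' <= i} with
#' \code{A[i'] < t}, or \code{NA} when no such position exists.  Note the
#' non-strict \code{i' <= i}: the query position itself qualifies, unlike the
#' classic PSV.
#'
#' @param a integer array.
#' @param i query position, \code{1 <= i <= length(a)}.
#' @param t threshold.
#' @return index or \code{NA_integer_}.
#' @export
psv_threshold <- function(a, i, t) {
  if (i < 1L || i > length(a)) stop("index out of range")
  while (i >= 1L && a[i] >= t) i <- i - 1L
  if (i < 1L) NA_integer_ else i
}

#' Threshold next-smaller-value query
#'
#' Mirror of \code{\link{psv_threshold}}: smallest \code{i' >= i} with
#' \code{A[i'] < t}.  Querying at \code{i = length(a) + 1} returns
#' \code{length(a) + 1} (virtual sentinel), so the left-contraction formula
#' may always pass \code{e' + 1}.
#'
#' @inheritParams psv_threshold
#' @export
nsv_threshold <- function(a, i, t) {
  n <- length(a)
  if (i < 1L || i > n + 1L) stop("index out of range")
  if (i == n + 1L) return(n + 1L)
  while (i <= n && a[i] >= t) i <- i + 1L
  if (i > n) NA_integer_ else i
}

#' Sum of the LCP array
#'
#' A repetitiveness measure: \code{(n^2 + n)/2 - lcpsum} equals the number of
#' distinct substrings of the indexed string.
#'
#' @param lcp integer LCP array.
#' @return the sum, as a double (can exceed integer range).
#' @export
lcpsum <- function(lcp) sum(as.numeric(lcp))

#' Build a reference index
#'
#' Bundles everything the matching-statistics computation needs on the
#' reference side: the (augmented) reference, its suffix array, inverse and
#' LCP array, and the blockwise LCP maxima \code{M} for the leaf-branch fast
#' path.
#'
#' @param ref reference string; a terminal \code{"#"} is appended if absent.
#' @param collection optional \code{\link{string_collection}}; when given,
#'   the reference is augmented so every collection symbol occurs in it, and
#'   the symbol order covers both.
#' @param block_size LCP block size \code{b}; default chosen so that \code{M}
#'   has at most 4096 entries (16 KiB at 4 bytes each).
#' @return an object of class \code{reference_index} with fields \code{ref},
#'   \code{n}, \code{alph}, \code{rint} (integer-encoded reference),
#'   \code{SA}, \code{ISA}, \code{LCP}, \code{M}, \code{b}, \code{orig_len},
#'   \code{plcp_used}.
#' @examples
#' idx <- reference_index("TGATGGCACAGATACT")
#' idx$SA[1]   # rank 1 is the '#' suffix
#' @export
reference_index <- function(ref, collection = NULL, block_size = NULL) {
  if (!endsWith(ref, REFERENCE_SENTINEL)) ref <- paste0(ref, REFERENCE_SENTINEL)
  orig_len <- nchar(ref)
  if (!is.null(collection)) {
    aug <- augment_reference(ref, collection)
    ref <- aug$ref
  }
  alph <- if (is.null(collection)) {
    syms <- setdiff(unique(strsplit(ref, "", fixed = TRUE)[[1L]]),
                    c(REFERENCE_SENTINEL, COLLECTION_SENTINEL))
    c(REFERENCE_SENTINEL, COLLECTION_SENTINEL, sort(syms, method = "radix"))
  } else {
    symbol_order(collection, ref)
  }
  rint <- encode_symbols(ref, alph)
  n <- length(rint)
  if (rint[n] != 1L || sum(rint == 1L) != 1L) {
    stop("reference sentinel '#' must occur exactly once, at the end")
  }
  sa <- suffix_array_int(rint)
  isa <- build_inverse(sa)
  lcp <- build_lcp(rint, sa)
  b <- if (is.null(block_size)) max(1L, as.integer(ceiling(n / 4096))) else {
    if (block_size < 1L) stop("block size must be >= 1")
    as.integer(block_size)
  }
  structure(list(ref = ref, n = n, alph = alph, rint = rint,
                 SA = sa, ISA = isa, LCP = lcp,
                 M = build_block_max(lcp, b), b = b,
                 orig_len = orig_len, plcp_used = FALSE),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("Reference index: n =", x$n,
      "(", x$orig_len, "before augmentation ), sigma =",
      length(x$alph) - 2L, "\n")
  cat("  LCP block size b =", x$b, "; |M| =", length(x$M),
      "; max(LCP) =", max(x$LCP), "; LCPsum =", lcpsum(x$LCP), "\n")
  invisible(x)
}
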