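# Compressed stores of (insert-)head records, with a two-layer sampled +
# differential predecessor structure, and O(1)-shape reconstruction of the
# matching statistics / enhanced matching statistics at arbitrary positions.

#' Two-layer predecessor index
#'
#' Stores a strictly increasing set of positions as every \code{b_p}-th
#' position (sampled array, binary-searched) plus a differential encoding of
#' all positions (scanned and summed within a sample block).  Query cost is
#' \code{O(log(n/b_p) + b_p)}.
#'
#' @param positions strictly increasing integer vector (gaps must fit in a
#'   32-bit integer; violations are an error).
#' @param b_p sampling rate, \code{>= 1} (default 32).
#' @return object of class \code{predecessor_index}.
#' @export
predecessor_index <- function(positions, b_p = 32L) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("cannot index an empty position set")
  if (b_p < 1L) stop("`b_p` must be >= 1")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  gaps <- diff(positions)
  if (anyNA(gaps)) stop("position gap overflows 32-bit integer storage")
  structure(list(samples = positions[seq(1L, length(positions), by = b_p)],
                 first = positions[1L],
                 gaps = c(positions[1L], gaps),  # gaps[1] anchors the set
                 b_p = as.integer(b_p),
                 n = length(positions)),
            class = "predecessor_index")
}

#' Predecessor query
#'
#' Largest stored position \code{<= x}.  Binary search in the sampled array,
#' then a forward scan summing differential gaps.
#'
#' @param px a \code{\link{predecessor_index}}.
#' @param x query position (must be \code{>=} the smallest stored position).
#' @return the predecessor, with attribute \code{idx} giving its ordinal
#'   among the stored positions.
#' @export
predecessor <- function(px, x) {
  if (x < px$first) stop("query position ", x, " precedes every stored position")
  si <- findInterval(x, px$samples)
  i <- (si - 1L) * px$b_p + 1L
  val <- px$samples[si]
  while (i < px$n && val + px$gaps[i + 1L] <= x) {
    i <- i + 1L
    val <- val + px$gaps[i]
  }
  structure(val, idx = i)
}

# ordinal of the predecessor head for each (sorted or unsorted) query
# position; vectorised fast path used internally
pred_ordinal <- function(positions, x) findInterval(x, positions)

#' Compressed matching statistics store
#'
#' Stores, per document, the head positions with their \code{(p, ell)}
#' entries and a predecessor index over the heads.  Heads are the positions
#' where the matching-statistics length breaks the decrement run; every
#' other entry is recovered by \code{\link{ms_at}}.
#'
#' @param collection a \code{\link{string_collection}}.
#' @param idx a \code{\link{reference_index}} built with this collection.
#' @param b_p predecessor sampling rate.
#' @param fast_path passed to \code{\link{matching_statistics}}.
#' @return object of class \code{cms_store}; element \code{chi} holds the
#'   per-document head counts.
#' @export
cms_store <- function(collection, idx, b_p = 32L, fast_path = TRUE) {
  docs <- lapply(seq_len(collection$m), function(d) {
    ms <- matching_statistics(collection$docs[d], idx, fast_path = fast_path)
    h <- ms[ms$is_head, , drop = FALSE]
    list(j = h$i, p = h$p, ell = h$ell,
         px = predecessor_index(h$i, b_p = b_p),
         len = nrow(ms))
  })
  structure(list(docs = docs, m = collection$m,
                 chi = vapply(docs, function(x) length(x$j), 0L)),
            class = "cms_store")
}

#' Reconstruct a matching-statistics entry from the CMS
#'
#' \code{MS[i] = (p_j + k, ell_j - k)} where \code{j} is the head preceding
#' \code{i} (predecessor query) and \code{k = i - j}.  An entry of length 0
#' reports occurrence \code{-1} (empty factor).
#'
#' @param store a \code{\link{cms_store}}.
#' @param i text position.
#' @param d document index (default 1).
#' @return list with \code{p} and \code{ell}.
#' @export
ms_at <- function(store, i, d = 1L) {
  doc <- store$docs[[d]]
  if (i < 1L || i > doc$len) stop("position out of range")
  pr <- predecessor(doc$px, i)
  hi <- attr(pr, "idx")
  k <- i - doc$j[hi]
  ell <- doc$ell[hi] - k
  list(p = if (ell == 0L) -1L else doc$p[hi] + k, ell = ell)
}

#' Enhanced compressed matching statistics store
#'
#' The multi-document eCMS: per document, the insert-head positions with
#' their \code{(q, ell, x, c)} entries, a predecessor index over them, and
#' the reference index needed for the one ISA lookup that turns a
#' reconstructed \code{q} into an insert point.  Also retains which
#' insert-heads are plain heads, and per-document fast-path tallies.
#'
#' @inheritParams cms_store
#' @return object of class \code{ecms_store}; \code{chi_prime} holds the
#'   per-document insert-head counts, \code{chi} the head counts.
#' @export
ecms_store <- function(collection, idx, b_p = 32L, fast_path = TRUE) {
  docs <- lapply(seq_len(collection$m), function(d) {
    ms <- matching_statistics(collection$docs[d], idx, fast_path = fast_path)
    h <- ms[ms$is_ihead, , drop = FALSE]
    list(j = h$i, q = h$q, ell = h$ell, x = h$x, c = h$c,
         crank = encode_symbols(paste(h$c, collapse = ""), idx$alph),
         is_head = h$is_head,
         px = predecessor_index(h$i, b_p = b_p),
         len = nrow(ms))
  })
  structure(list(docs = docs, m = collection$m, idx = idx,
                 chi = vapply(docs, function(x) sum(x$is_head), 0L),
                 chi_prime = vapply(docs, function(x) length(x$j), 0L)),
            class = "ecms_store")
}

#' @export
print.ecms_store <- function(x, ...) {
  cat("eCMS store:", x$m, "documents;",
      sum(x$chi), "heads,", sum(x$chi_prime), "insert-heads\n")
  invisible(x)
}

#' Reconstruct an enhanced entry from the eCMS
#'
#' \code{ems(i) = (q_j + k, ell_j - k, x_j, c_j)} from the preceding
#' insert-head \code{j} with \code{k = i - j}; the insert point is the one
#' extra lookup \code{ip(i) = ISA[q_j + k]}.
#'
#' @param store an \code{\link{ecms_store}}.
#' @param d document index.
#' @param i text position.
#' @return list with \code{q}, \code{ell}, \code{x}, \code{c}, \code{crank}
#'   and \code{ip}.
#' @export
ems_at <- function(store, d, i) {
  doc <- store$docs[[d]]
  if (i < 1L || i > doc$len) stop("position out of range")
  pr <- predecessor(doc$px, i)
  hi <- attr(pr, "idx")
  k <- i - doc$j[hi]
  q <- doc$q[hi] + k
  list(q = q, ell = doc$ell[hi] - k, x = doc$x[hi], c = doc$c[hi],
       crank = doc$crank[hi], ip = store$idx$ISA[q])
}

# vectorised ems over positions `is` of document d (same math as ems_at,
# predecessor resolved with findInterval)
ems_block <- function(store, d, is) {
  doc <- store$docs[[d]]
  hi <- pred_ordinal(doc$j, is)
  k <- is - doc$j[hi]
  q <- doc$q[hi] + k
  list(q = q, ell = doc$ell[hi] - k, x = doc$x[hi], crank = doc$crank[hi],
       ip = store$idx$ISA[q])
}
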