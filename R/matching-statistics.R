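# Matching statistics of a document against the reference index, via right
# extensions (binary searches in SA order) and left contractions (one ISA
# step per interval end plus threshold PSV/NSV on the LCP array), with the
# leaf-branch fast path driven by the blockwise LCP maxima.

# first rank j in [lo..hi] whose suffix has symbol >= c at offset `depth`
lower_bound_rank <- function(rint, sa, lo, hi, depth, c) {
  hi <- hi + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (rint[sa[mid] + depth] < c) lo <- mid + 1L else hi <- mid
  }
  lo
}

# first rank j in [lo..hi] whose suffix has symbol > c at offset `depth`
upper_bound_rank <- function(rint, sa, lo, hi, depth, c) {
  hi <- hi + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (rint[sa[mid] + depth] <= c) lo <- mid + 1L else hi <- mid
  }
  lo
}

#' Right extension of a suffix-array interval
#'
#' Computes the \code{Yc}-interval from the \code{Y}-interval via two binary
#' searches at character offset \code{depth}.  When the extension is empty,
#' the SA rank at which \code{Yc}-prefixed suffixes would be inserted is
#' returned instead.
#'
#' @param idx a \code{\link{reference_index}}.
#' @param iv list with \code{s}, \code{e} (inclusive SA bounds) and
#'   \code{depth} (\code{= |Y|}).
#' @param c a single character.
#' @return list with \code{s}, \code{e}, \code{depth} of the
#'   \code{Yc}-interval and \code{empty = FALSE}; or, for an empty
#'   extension, \code{empty = TRUE} plus \code{insert}, the SA rank where
#'   \code{Yc} would slot in.
#' @export
right_extension <- function(idx, iv, c) {
  code <- encode_symbols(c, idx$alph)
  lb <- lower_bound_rank(idx$rint, idx$SA, iv$s, iv$e, iv$depth, code)
  ub <- upper_bound_rank(idx$rint, idx$SA, iv$s, iv$e, iv$depth, code)
  if (lb > ub - 1L) {
    list(empty = TRUE, insert = lb, depth = iv$depth)
  } else {
    list(s = lb, e = ub - 1L, depth = iv$depth + 1L, empty = FALSE)
  }
}

#' Left contraction of a suffix-array interval
#'
#' Given the \code{cY}-interval \code{SA[s..e]} of depth \code{>= 1},
#' computes the \code{Y}-interval: take \code{s' = ISA[SA[s]+1]},
#' \code{e' = ISA[SA[e]+1]} (both lie inside the target) and widen with
#' threshold PSV/NSV queries on the LCP array —
#' \code{[PSV(LCP, s', |Y|) .. NSV(LCP, e'+1, |Y|) - 1]}.
#'
#' @inheritParams right_extension
#' @return list with \code{s}, \code{e}, \code{depth} of the
#'   \code{Y}-interval.
#' @export
left_contraction <- function(idx, iv) {
  if (iv$depth < 1L) stop("cannot contract an interval of depth 0")
  newdepth <- iv$depth - 1L
  if (newdepth == 0L) return(list(s = 1L, e = idx$n, depth = 0L))
  sp <- idx$ISA[idx$SA[iv$s] + 1L]
  ep <- idx$ISA[idx$SA[iv$e] + 1L]
  s <- psv_threshold(idx$LCP, sp, newdepth)
  e_nsv <- nsv_threshold(idx$LCP, ep + 1L, newdepth)
  e <- (if (is.na(e_nsv)) idx$n + 1L else e_nsv) - 1L
  list(s = s, e = e, depth = newdepth)
}

# fast-path guard: the contracted interval [j0..j0] is the full Y-interval
# when both boundary LCP entries are < newdepth; checked conservatively via
# the block maxima covering j0 and j0+1.
fast_path_ok <- function(j0, newdepth, M, b, n) {
  k0 <- (j0 - 1L) %/% b + 1L
  if (newdepth <= M[k0]) return(FALSE)
  if (j0 + 1L > n) return(TRUE)
  k1 <- j0 %/% b + 1L
  k1 == k0 || newdepth > M[k1]
}

# Streaming computation over one integer-encoded document (must end with the
# '$' rank 2, which never occurs in the reference).  Returns per-position
# vectors: p, ell, ip, q, xS (TRUE = S), crank, is_head, is_ihead, and the
# fast-path hit count.
ms_stream <- function(sint, idx, fast_path = TRUE) {
  rint <- idx$rint; sa <- idx$SA; isa <- idx$ISA; lcp <- idx$LCP
  n <- idx$n; M <- idx$M; b <- idx$b
  len <- length(sint)
  p <- integer(len); ell <- integer(len); ip <- integer(len)
  xS <- logical(len); crank <- integer(len)
  fast_hits <- 0L
  s <- 1L; e <- n; depth <- 0L
  for (i in seq_len(len)) {
    # extend with successive characters of S[i..] until the extension fails
    repeat {
      pos <- i + depth
      cc <- sint[pos]
      lb <- lower_bound_rank(rint, sa, s, e, depth, cc)
      ub <- upper_bound_rank(rint, sa, lb, e, depth, cc)
      if (lb > ub - 1L) break
      s <- lb; e <- ub - 1L; depth <- depth + 1L
    }
    ell[i] <- depth
    crank[i] <- cc
    if (depth == 0L) {
      if (cc != 2L) {
        stop("symbol '", idx$alph[cc],
             "' of the document does not occur in the reference ",
             "(reference not augmented?)")
      }
      p[i] <- -1L
      ip[i] <- 1L          # empty matching factor slots at rank 1
      xS[i] <- FALSE       # '$' > '#', so the suffix is Larger
    } else {
      # heads report the leftmost-rank occurrence; inside a decrement run the
      # tracked occurrence advances with the factor, matching what
      # reconstruction from the preceding head yields
      p[i] <- if (i > 1L && depth == ell[i - 1L] - 1L) p[i - 1L] + 1L
              else sa[s]
      if (lb - 1L >= s) {  # some U-occurrence is < Uc: its greatest rank
        ip[i] <- lb - 1L
        xS[i] <- FALSE
      } else {             # all U-occurrences exceed Uc: smallest rank
        ip[i] <- s
        xS[i] <- TRUE
      }
    }
    # transition to position i+1: drop the first character of the factor
    if (depth <= 1L) {
      s <- 1L; e <- n; depth <- 0L
    } else {
      newdepth <- depth - 1L
      j0 <- isa[sa[s] + 1L]
      if (fast_path && fast_path_ok(j0, newdepth, M, b, n)) {
        s <- j0; e <- j0
        fast_hits <- fast_hits + 1L
      } else {
        sp <- j0
        ep <- isa[sa[e] + 1L]
        ii <- sp
        while (lcp[ii] >= newdepth) ii <- ii - 1L
        s <- ii
        ii <- ep + 1L
        while (ii <= n && lcp[ii] >= newdepth) ii <- ii + 1L
        e <- ii - 1L
      }
      depth <- newdepth
    }
  }
  q <- sa[ip]
  is_head <- c(TRUE, ell[-1L] > ell[-len] - 1L)
  is_ihead <- c(TRUE, q[-1L] != q[-len] + 1L)
  # The sentinel is always recorded as an insert-head.  When a document
  # suffix matches a reference suffix through to the end, the q-run reaches
  # the sentinel unbroken and the tie-break recursion (which moves to the
  # insert-head covering the mismatch character) would otherwise land on
  # heads at different offsets in the two documents.  A sentinel record is
  # exactly what reconstruction from the previous head yields, so storing it
  # changes no reconstructed value.
  is_ihead[len] <- TRUE
  list(p = p, ell = ell, ip = ip, q = as.integer(q), xS = xS,
       crank = crank, is_head = is_head, is_ihead = is_ihead,
       fast_hits = fast_hits)
}

#' Matching statistics of a document against a reference index
#'
#' For every position \code{i} of \code{s}, the matching factor is the
#' longest prefix of \code{s[i..]} occurring in the reference.  The returned
#' table carries the plain matching statistics (\code{p}: an occurrence of
#' the factor, leftmost in SA order; \code{ell}: its length) and the enhanced
#' entries: the insert point \code{ip} (lexicographic rank the suffix would
#' take among reference suffixes), \code{q = SA[ip]}, the side flag \code{x}
#' (\code{"S"}: factor + mismatch character sorts below the \code{q}-suffix;
#' \code{"L"}: above) and the mismatch character \code{c}.  Head positions
#' (where \code{ell} breaks the decrement run) and insert-head positions
#' (where \code{q} breaks the \code{+1} run) are flagged.
#'
#' @param s document string; a terminal \code{"$"} is appended if absent.
#' @param idx a \code{\link{reference_index}} covering all symbols of
#'   \code{s} (build it with the collection to guarantee augmentation).
#' @param fast_path use the leaf-branch heuristic for left contractions
#'   (results are identical either way; this is a speed knob only).
#' @return data.frame with one row per position: \code{i}, \code{p},
#'   \code{ell}, \code{ip}, \code{q}, \code{x}, \code{c}, \code{is_head},
#'   \code{is_ihead}.  Attribute \code{fast_hits} counts fast-path
#'   contractions taken.
#' @examples
#' cc <- string_collection("GATGGCACATTGATGG")
#' idx <- reference_index("TGATGGCACAGATACT", cc)
#' ms <- matching_statistics("GATGGCACATTGATGG", idx)
#' ms[ms$is_head, c("i", "p", "ell")]
#' @export
matching_statistics <- function(s, idx, fast_path = TRUE) {
  if (!inherits(idx, "reference_index")) stop("`idx` must be a reference_index")
  s <- toupper(s)
  if (!endsWith(s, COLLECTION_SENTINEL)) s <- paste0(s, COLLECTION_SENTINEL)
  sint <- encode_symbols(s, idx$alph)
  if (any(sint[-length(sint)] == 2L)) stop("'$' may only terminate the document")
  missing <- setdiff(unique(sint[-length(sint)]), unique(idx$rint))
  if (length(missing) > 0L) {
    stop("symbol '", idx$alph[missing[1L]],
         "' does not occur in the reference; augment the reference first")
  }
  st <- ms_stream(sint, idx, fast_path = fast_path)
  out <- data.frame(i = seq_along(sint), p = st$p, ell = st$ell,
                    ip = st$ip, q = st$q,
                    x = ifelse(st$xS, "S", "L"),
                    c = idx$alph[st$crank],
                    is_head = st$is_head, is_ihead = st$is_ihead,
                    stringsAsFactors = FALSE)
  attr(out, "fast_hits") <- st$fast_hits
  out
}

#' Insert point of a single position
#'
#' Applies the three-case insert-point definition directly to a matching
#' factor \code{U} (given by its SA interval) and mismatch character: rank 1
#' when \code{U} is empty; otherwise the greatest rank in the
#' \code{U}-interval whose suffix sorts below \code{Uc} when one exists
#' (flag \code{"L"}), else the smallest rank of the interval (flag
#' \code{"S"}).
#'
#' @param idx a \code{\link{reference_index}}.
#' @param iv the \code{U}-interval as for \code{\link{right_extension}}, or
#'   \code{NULL} for an empty factor.
#' @param c the mismatch character.
#' @return list with \code{ip} (SA rank), \code{q = SA[ip]} and \code{x}.
#' @export
compute_insert_point <- function(idx, iv, c) {
  code <- encode_symbols(c, idx$alph)
  if (is.null(iv) || iv$depth == 0L) {
    return(list(ip = 1L, q = idx$SA[1L], x = if (code > 1L) "L" else "S"))
  }
  lb <- lower_bound_rank(idx$rint, idx$SA, iv$s, iv$e, iv$depth, code)
  if (lb - 1L >= iv$s) {
    list(ip = lb - 1L, q = idx$SA[lb - 1L], x = "L")
  } else {
    list(ip = iv$s, q = idx$SA[iv$s], x = "S")
  }
}

#' Enhanced compressed matching statistics of one document
#'
#' Runs \code{\link{matching_statistics}} and keeps only the insert-head
#' records — the rows from which every other position's enhanced entry can
#' be reconstructed by offsetting (see \code{\link{ems_at}}).  Position 1 is
#' always an insert-head, and every head is an insert-head.
#'
#' @inheritParams matching_statistics
#' @return data.frame of insert-head rows (columns as in
#'   \code{\link{matching_statistics}}).
#' @export
compute_ecms <- function(s, idx, fast_path = TRUE) {
  ms <- matching_statistics(s, idx, fast_path = fast_path)
  ms[ms$is_ihead, , drop = FALSE]
}
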