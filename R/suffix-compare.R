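# Ordering collection suffixes from their enhanced matching statistics:
# smaller insert point wins outright; at equal insert points the factor
# length, side flag and mismatch character decide.  A full tie means both
# suffixes share their matching factor plus mismatch character — a prefix of
# known equal length ell — so the comparison recurses at the aligned
# stripped positions (i + ell, i' + ell).  Content-equal suffixes reach
# their sentinels in lockstep and are ordered by document index, matching
# the GSA convention.

#' Compare two suffixes by their enhanced matching statistics
#'
#' Implements the partial order: a smaller insert point sorts first; at
#' equal insert points, a shorter factor with flag \code{"S"} sorts first
#' and a shorter factor with flag \code{"L"} sorts last; at equal lengths,
#' \code{"S"} precedes \code{"L"}; at equal length and flag, the mismatch
#' characters decide.  The outcome \code{0} (a tie) occurs only when insert
#' point, length, flag and mismatch character all coincide — lexicographic
#' order is then not yet decided (see \code{\link{compare_full}}).
#'
#' @param a,b lists with fields \code{ip}, \code{ell}, \code{x} and
#'   \code{crank} (mismatch-character rank), as returned by
#'   \code{\link{ems_at}}.
#' @return \code{-1L} (a sorts first), \code{1L} (b sorts first) or
#'   \code{0L} (tie).
#' @export
compare_ems <- function(a, b) {
  if (a$ip != b$ip) return(if (a$ip < b$ip) -1L else 1L)
  if (a$ell != b$ell) {
    if (a$ell < b$ell) return(if (a$x == "S") -1L else 1L)
    return(if (b$x == "S") 1L else -1L)
  }
  if (a$x != b$x) return(if (a$x == "S") -1L else 1L)
  if (a$crank != b$crank) return(if (a$crank < b$crank) -1L else 1L)
  0L
}

# insert-head ordinal covering position i of document d
ihead_ordinal <- function(store, d, i) {
  pred_ordinal(store$docs[[d]]$j, i)
}

#' Full suffix comparison via the eCMS
#'
#' Resolves the order of two collection suffixes by iterating the enhanced
#' comparison.  On a tie, both suffixes share their matching factor plus
#' mismatch character, a common prefix of equal length \code{ell}, so the
#' comparison restarts at the stripped positions \code{i + ell} and
#' \code{i' + ell} — the same offset on both sides, kept aligned by
#' construction.  A tie with \code{ell = 0} means both suffixes sit at
#' their sentinels (the contents were equal throughout) and is broken by
#' document index, matching the GSA convention.
#'
#' @param a,b integer vectors \code{c(d, i)}: document index and position.
#' @param store an \code{\link{ecms_store}}.
#' @return \code{-1L} if suffix \code{a} precedes \code{b} in the GSA,
#'   \code{1L} otherwise; \code{0L} only for the identical coordinate.
#' @export
compare_full <- function(a, b, store) {
  d <- a[1L]; i <- a[2L]; d2 <- b[1L]; i2 <- b[2L]
  max_steps <- min(store$docs[[d]]$len - i, store$docs[[d2]]$len - i2) + 2L
  steps <- 0L
  repeat {
    if (d == d2 && i == i2) return(0L)
    ea <- ems_at(store, d, i)
    eb <- ems_at(store, d2, i2)
    cmp <- compare_ems(ea, eb)
    if (cmp != 0L) return(cmp)
    if (ea$ell == 0L) {        # both at sentinels: content-equal suffixes
      return(if (d < d2) -1L else 1L)
    }
    j <- i + ea$ell; j2 <- i2 + eb$ell
    if (j - i != j2 - i2) {
      stop("internal error: tie recursion lost offset alignment")
    }
    i <- j; i2 <- j2
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("internal error: comparison exceeded the position budget")
    }
  }
}

#' Suffix comparison given ranked insert-heads
#'
#' Same contract as \code{\link{compare_full}}, but whenever the tie
#' recursion lands with both sides on an insert-head, the precomputed total
#' order of the insert-heads (\code{\link{rank_heads}}) settles the
#' comparison with one rank lookup per side.  Comparisons launched from
#' positions whose covering insert-heads tie on content — notably whole
#' duplicated documents — short-circuit this way instead of walking to the
#' sentinels.
#'
#' @inheritParams compare_full
#' @param head_rank a \code{head_rank} object from \code{\link{rank_heads}}.
#' @return \code{-1L} or \code{1L} (\code{0L} only for identical coordinates).
#' @export
compare_with_ranks <- function(a, b, store, head_rank) {
  if (is.null(head_rank)) stop("`head_rank` is required; run rank_heads() first")
  d <- a[1L]; i <- a[2L]; d2 <- b[1L]; i2 <- b[2L]
  max_steps <- min(store$docs[[d]]$len - i, store$docs[[d2]]$len - i2) + 2L
  steps <- 0L
  repeat {
    if (d == d2 && i == i2) return(0L)
    ha <- ihead_ordinal(store, d, i)
    hb <- ihead_ordinal(store, d2, i2)
    if (store$docs[[d]]$j[ha] == i && store$docs[[d2]]$j[hb] == i2) {
      ra <- head_rank$per_doc[[d]][ha]
      rb <- head_rank$per_doc[[d2]][hb]
      if (ra != rb) return(if (ra < rb) -1L else 1L)
      return(if (d < d2) -1L else 1L)   # same rank: identical head content
    }
    ea <- ems_at(store, d, i)
    eb <- ems_at(store, d2, i2)
    cmp <- compare_ems(ea, eb)
    if (cmp != 0L) return(cmp)
    if (ea$ell == 0L) return(if (d < d2) -1L else 1L)
    i <- i + ea$ell; i2 <- i2 + eb$ell
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("internal error: comparison exceeded the position budget")
    }
  }
}
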