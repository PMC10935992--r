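# Six-phase GSA construction: reference structures (Phase 1), eCMS
# (Phase 2), S*-selection and bucketing by insert point (Phase 3), total
# order of the insert-heads via partial sort + metacharacter string
# (Phase 4), bucket-local S* sorting (Phase 5), induced sorting (Phase 6).

#' Classify every collection suffix as S, L or S*
#'
#' One back-to-front scan per document: a suffix is S-type when smaller than
#' its successor suffix, L-type when larger (equal characters inherit the
#' successor's type).  An S-type suffix with an L-type predecessor is S*.
#' The sentinel suffix is S-type and always S* (its predecessor character
#' exceeds \code{"$"}, hence is L-type; a length-1 document keeps the S* mark
#' by convention so that every document seeds the induction).
#'
#' @param collection a \code{\link{string_collection}}.
#' @return list of character vectors over \code{c("S", "L", "S*")}, one per
#'   document.
#' @examples
#' classify_types(string_collection("GATC"))
#' @export
classify_types <- function(collection) {
  alph <- symbol_order(collection)
  lapply(collection$docs, function(doc) {
    v <- encode_symbols(doc, alph)
    n <- length(v)
    t <- character(n)
    t[n] <- "S"
    if (n > 1L) {
      for (i in (n - 1L):1L) {
        t[i] <- if (v[i] < v[i + 1L]) "S"
                else if (v[i] > v[i + 1L]) "L"
                else t[i + 1L]
      }
      star <- c(FALSE, t[-1L] == "S" & t[-n] == "L")
      t[star] <- "S*"
      if (t[n - 1L] == "L") t[n] <- "S*"
    } else {
      t[1L] <- "S*"
    }
    t
  })
}

# all S* coordinates with their ems keys, as one data.frame
sstar_table <- function(collection, types, store) {
  out <- lapply(seq_len(collection$m), function(d) {
    is <- which(types[[d]] == "S*")
    if (length(is) == 0L) return(NULL)
    e <- ems_block(store, d, is)
    data.frame(d = d, i = is, ip = e$ip, q = e$q, ell = e$ell,
               x = e$x, crank = e$crank, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bucket the S*-suffixes by insert point
#'
#' Every S*-suffix lands in the bucket of its insert point (reconstructed
#' from the eCMS); buckets are emitted in increasing insert-point order, so
#' their concatenation is already globally ordered across buckets — only the
#' inside of each bucket remains to be sorted.
#'
#' @param collection a \code{\link{string_collection}}.
#' @param types output of \code{\link{classify_types}}.
#' @param store an \code{\link{ecms_store}}.
#' @return list of buckets; each a list with \code{ip}, \code{q} and a
#'   data.frame \code{members} (columns \code{d}, \code{i}, \code{ell},
#'   \code{x}, \code{crank}).
#' @export
bucket_sstar <- function(collection, types, store) {
  tab <- sstar_table(collection, types, store)
  split_idx <- split(seq_len(nrow(tab)), tab$ip)
  lapply(split_idx, function(rows) {
    list(ip = tab$ip[rows[1L]], q = tab$q[rows[1L]],
         members = tab[rows, c("d", "i", "ell", "x", "crank")])
  })
}

# gather all insert-heads of the store into one data.frame
all_heads <- function(store) {
  do.call(rbind, lapply(seq_len(store$m), function(d) {
    doc <- store$docs[[d]]
    ords <- seq_along(doc$j)
    data.frame(d = d, hidx = ords, j = doc$j,
               ip = store$idx$ISA[doc$q], ell = doc$ell, x = doc$x,
               crank = doc$crank, stringsAsFactors = FALSE)
  }))
}

#' Partial sort of the insert-heads
#'
#' Orders all insert-heads of the collection by the composite key implied by
#' the enhanced comparison: insert point first, then flag (\code{"S"} before
#' \code{"L"}), then factor length — ascending within \code{"S"}, descending
#' within \code{"L"} — then mismatch character.  Heads with identical keys
#' share a rank (dense ranks); rank values start above the per-document
#' terminator values \code{1..m} reserved for the metastring.
#'
#' @param store an \code{\link{ecms_store}}.
#' @return data.frame of all insert-heads (\code{d}, \code{hidx}, \code{j},
#'   key columns) with a \code{prank} column of dense partial ranks.
#' @export
partial_sort_heads <- function(store) {
  h <- all_heads(store)
  xnum <- ifelse(h$x == "S", 0L, 1L)
  sgnell <- ifelse(h$x == "S", h$ell, -h$ell)
  o <- order(h$ip, xnum, sgnell, h$crank, method = "radix")
  key_change <- c(TRUE,
                  h$ip[o[-1L]] != h$ip[o[-length(o)]] |
                  xnum[o[-1L]] != xnum[o[-length(o)]] |
                  sgnell[o[-1L]] != sgnell[o[-length(o)]] |
                  h$crank[o[-1L]] != h$crank[o[-length(o)]])
  pr <- integer(nrow(h))
  pr[o] <- cumsum(key_change) + store$m  # 1..m reserved for terminators
  h$prank <- pr
  h
}

#' Build the metacharacter string
#'
#' Per document, the partial ranks of its insert-heads in text order,
#' followed by that document's terminator (value \code{d}, below every head
#' rank and ordered by document index — mirroring the \code{"$"} tie rule);
#' documents are concatenated in index order.
#'
#' @param ranked output of \code{\link{partial_sort_heads}}.
#' @param m number of documents.
#' @return list with \code{meta} (integer vector), and parallel vectors
#'   \code{d}, \code{hidx} mapping metastring positions back to insert-heads
#'   (\code{hidx = 0} marks a terminator).
#' @export
build_meta_string <- function(ranked, m) {
  meta <- integer(0L); dd <- integer(0L); hh <- integer(0L)
  for (d in seq_len(m)) {
    hd <- ranked[ranked$d == d, , drop = FALSE]
    hd <- hd[order(hd$j), , drop = FALSE]
    meta <- c(meta, hd$prank, d)
    dd <- c(dd, rep(d, nrow(hd)), d)
    hh <- c(hh, hd$hidx, 0L)
  }
  list(meta = meta, d = dd, hidx = hh)
}

#' Total order of the insert-heads
#'
#' Refines the partial sort into a total lexicographic order of the
#' insert-head suffixes.  Heads with distinct partial ranks are already
#' ordered (their enhanced entries differ, so the partial order decides);
#' groups sharing a partial rank tie on their entire enhanced entry and are
#' ordered with the full comparator, whose tie recursion strips the shared
#' factor-plus-mismatch prefix until the suffixes diverge (content-equal
#' heads end up in document order).  All final ranks are distinct.
#'
#' @param meta output of \code{\link{build_meta_string}}.
#' @param store the \code{\link{ecms_store}} the heads came from.
#' @return object of class \code{head_rank}: list \code{per_doc} of integer
#'   rank vectors aligned with each document's insert-head list.
#' @export
rank_heads <- function(meta, store) {
  keep <- meta$hidx > 0L            # drop terminator slots
  d <- meta$d[keep]; hidx <- meta$hidx[keep]; prank <- meta$meta[keep]
  o <- order(prank, method = "radix")
  total <- integer(length(o))       # total[t] = ordinal of t-th head in `o`
  t0 <- 1L
  n <- length(o)
  while (t0 <= n) {
    t1 <- t0
    while (t1 < n && prank[o[t1 + 1L]] == prank[o[t0]]) t1 <- t1 + 1L
    if (t1 > t0) {
      grp <- o[t0:t1]
      coords <- lapply(grp, function(g) {
        c(d[g], store$docs[[d[g]]]$j[hidx[g]])
      })
      # insertion sort with the full comparator (groups are small: they
      # share the complete enhanced entry)
      ord <- seq_along(grp)
      for (u in seq_along(ord)[-1L]) {
        v <- u
        while (v > 1L &&
               compare_full(coords[[ord[v - 1L]]], coords[[ord[v]]],
                            store) > 0L) {
          tmp <- ord[v - 1L]; ord[v - 1L] <- ord[v]; ord[v] <- tmp
          v <- v - 1L
        }
      }
      o[t0:t1] <- grp[ord]
    }
    t0 <- t1 + 1L
  }
  total[o] <- seq_len(n)
  per_doc <- lapply(split(seq_len(n), d), function(rows) {
    total[rows][order(hidx[rows])]
  })
  structure(list(per_doc = per_doc), class = "head_rank")
}

#' Sort the S*-buckets
#'
#' Sorts each bucket with the ranked comparison (insert point constant
#' within a bucket; flag, signed length and mismatch character decide, full
#' ties via one insert-head rank lookup, content-equal sentinels by document
#' index) and concatenates buckets in insert-point order.
#'
#' @param buckets output of \code{\link{bucket_sstar}}.
#' @param store an \code{\link{ecms_store}}.
#' @param head_rank output of \code{\link{rank_heads}}.
#' @return integer matrix with columns \code{d}, \code{j}: all S*-suffixes
#'   in GSA order.
#' @export
sort_sstar_buckets <- function(buckets, store, head_rank) {
  sorted <- lapply(buckets, function(bk) {
    mb <- bk$members
    if (nrow(mb) == 1L) return(cbind(d = mb$d, j = mb$i))
    xnum <- ifelse(mb$x == "S", 0L, 1L)
    sgnell <- ifelse(mb$x == "S", mb$ell, -mb$ell)
    o <- order(xnum, sgnell, mb$crank, method = "radix")
    # members with identical (flag, length, mismatch) tie on the whole
    # enhanced entry (ip is constant within a bucket); resolve those runs
    # with the ranked comparator
    t0 <- 1L
    n <- length(o)
    while (t0 <= n) {
      t1 <- t0
      while (t1 < n &&
             xnum[o[t1 + 1L]] == xnum[o[t0]] &&
             sgnell[o[t1 + 1L]] == sgnell[o[t0]] &&
             mb$crank[o[t1 + 1L]] == mb$crank[o[t0]]) t1 <- t1 + 1L
      if (t1 > t0) {
        grp <- o[t0:t1]
        ord <- seq_along(grp)
        for (u in seq_along(ord)[-1L]) {
          v <- u
          while (v > 1L) {
            ga <- grp[ord[v - 1L]]; gb <- grp[ord[v]]
            if (compare_with_ranks(c(mb$d[ga], mb$i[ga]),
                                   c(mb$d[gb], mb$i[gb]),
                                   store, head_rank) <= 0L) break
            tmp <- ord[v - 1L]; ord[v - 1L] <- ord[v]; ord[v] <- tmp
            v <- v - 1L
          }
        }
        o[t0:t1] <- grp[ord]
      }
      t0 <- t1 + 1L
    }
    cbind(d = mb$d[o], j = mb$i[o])
  })
  out <- do.call(rbind, sorted)
  dimnames(out) <- list(NULL, c("d", "j"))
  out
}

#' Induce the full GSA from the sorted S*-suffixes
#'
#' SAIS-style induction generalised to a collection: conceptual buckets by
#' first symbol (the \code{"$"} bucket, holding one sentinel per document in
#' document order, comes first), sorted S*-suffixes seeded at bucket tails,
#' then a left-to-right scan inducing L-type suffixes at bucket heads and a
#' right-to-left scan inducing S-type suffixes at bucket tails.
#'
#' @param sstar_sorted integer matrix (\code{d}, \code{j}) of all
#'   S*-suffixes in GSA order.
#' @param collection a \code{\link{string_collection}}.
#' @param types output of \code{\link{classify_types}}.
#' @return integer matrix with columns \code{d}, \code{j}: the GSA.
#' @export
induce_gsa <- function(sstar_sorted, collection, types) {
  alph <- symbol_order(collection)
  enc <- lapply(collection$docs, encode_symbols, alph = alph)
  ltype <- lapply(types, function(t) t == "L")
  nsym <- length(alph)
  counts <- integer(nsym)
  for (v in enc) counts <- counts + tabulate(v, nbins = nsym)
  bend <- cumsum(counts)
  bstart <- bend - counts + 1L
  N <- sum(counts)
  gd <- integer(N); gj <- integer(N)
  # seed sorted S* at bucket tails (reverse order keeps relative order)
  tl <- bend
  for (r in rev(seq_len(nrow(sstar_sorted)))) {
    d <- sstar_sorted[r, 1L]; j <- sstar_sorted[r, 2L]
    k <- enc[[d]][j]
    gd[tl[k]] <- d; gj[tl[k]] <- j
    tl[k] <- tl[k] - 1L
  }
  # induce L-type suffixes, left to right
  hd <- bstart
  for (r in seq_len(N)) {
    d <- gd[r]
    if (d > 0L) {
      j <- gj[r] - 1L
      if (j > 0L && ltype[[d]][j]) {
        k <- enc[[d]][j]
        gd[hd[k]] <- d; gj[hd[k]] <- j
        hd[k] <- hd[k] + 1L
      }
    }
  }
  # induce S-type suffixes, right to left (overwrites the S* seeds)
  tl <- bend
  for (r in N:1L) {
    d <- gd[r]
    if (d > 0L) {
      j <- gj[r] - 1L
      if (j > 0L && !ltype[[d]][j]) {
        k <- enc[[d]][j]
        gd[tl[k]] <- d; gj[tl[k]] <- j
        tl[k] <- tl[k] - 1L
      }
    }
  }
  if (any(gd == 0L)) stop("internal error: induction left unfilled GSA slots")
  cbind(d = gd, j = gj)
}

#' Build the generalized suffix array of a collection
#'
#' Runs the full six-phase pipeline: reference augmentation and indexing,
#' enhanced compressed matching statistics, S* classification and
#' insert-point bucketing, insert-head ranking via the metacharacter string,
#' bucket-local sorting, and induced sorting.  The result lists every
#' \code{(d, j)} suffix coordinate of the collection in lexicographic order,
#' ties broken by document index.  Reference suffixes are not part of the
#' output.
#'
#' @param collection a \code{\link{string_collection}} (or character vector,
#'   which is wrapped into one).
#' @param ref optional reference string; by default the first document (its
#'   \code{"$"} replaced by \code{"#"} in the indexed copy, while the
#'   document itself stays in the collection).
#' @param block_size,b_p,fast_path tuning knobs, see
#'   \code{\link{reference_index}}, \code{\link{ecms_store}} and
#'   \code{\link{matching_statistics}}.
#' @return object of class \code{gsa}: list with \code{gsa} (integer matrix,
#'   columns \code{d}, \code{j}), \code{m}, \code{N} and \code{stats}
#'   (head, insert-head, S* and bucket counts, fast-path tally).
#' @examples
#' g <- build_gsa(string_collection(c("GATTACA", "GATTACA")))
#' head(g$gsa)
#' @export
build_gsa <- function(collection, ref = NULL, block_size = NULL, b_p = 32L,
                      fast_path = TRUE) {
  if (!inherits(collection, "string_collection")) {
    collection <- string_collection(collection)
  }
  if (is.null(ref)) {
    d1 <- collection$docs[1L]
    ref <- substr(d1, 1L, nchar(d1) - 1L)  # drop '$'; '#' appended below
  }
  # Phase 1: reference structures (augmentation happens inside)
  idx <- reference_index(ref, collection, block_size = block_size)
  # Phase 2: eCMS of every document
  store <- ecms_store(collection, idx, b_p = b_p, fast_path = fast_path)
  # Phase 3: types and S* bucketing by insert point
  types <- classify_types(collection)
  buckets <- bucket_sstar(collection, types, store)
  # Phase 4: total order of the insert-heads
  ranked <- partial_sort_heads(store)
  meta <- build_meta_string(ranked, collection$m)
  hr <- rank_heads(meta, store)
  # Phase 5: sort the S* buckets
  sstar_sorted <- sort_sstar_buckets(buckets, store, hr)
  # Phase 6: induce the remaining suffixes
  g <- induce_gsa(sstar_sorted, collection, types)
  structure(list(gsa = g, m = collection$m, N = collection$N,
                 stats = list(n_heads = sum(store$chi),
                              n_iheads = sum(store$chi_prime),
                              n_sstar = nrow(sstar_sorted),
                              n_buckets = length(buckets))),
            class = "gsa")
}

#' @export
print.gsa <- function(x, ...) {
  cat("Generalized suffix array:", x$N, "suffixes over", x$m, "documents\n")
  cat("  heads:", x$stats$n_heads,
      " insert-heads:", x$stats$n_iheads,
      " S*:", x$stats$n_sstar,
      " buckets:", x$stats$n_buckets, "\n")
  invisible(x)
}
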