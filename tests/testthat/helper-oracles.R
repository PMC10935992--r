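# Brute-force oracles and fixture builders shared across the suite.  All
# string comparisons go through radix (C-collation) ordering so that
# '#' < '$' < letters regardless of locale.

`%||%` <- function(a, b) if (is.null(a)) b else a

str_lt <- function(a, b) {
  if (a == b) return(FALSE)
  identical(sort(c(a, b), method = "radix")[1L], a)
}

str_lt_vec <- function(av, b) {
  vapply(av, str_lt, logical(1L), b = b)
}

# sorted suffixes of a string: list(sa = permutation, suf = sorted suffixes)
oracle_suffixes <- function(x) {
  n <- nchar(x)
  suf <- substring(x, seq_len(n))
  o <- order(suf, method = "radix")
  list(sa = o, suf = suf[o])
}

# pairwise longest-common-prefix length of two strings
oracle_lcp_pair <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  l <- 0L
  while (l < n && substr(a, l + 1L, l + 1L) == substr(b, l + 1L, l + 1L)) {
    l <- l + 1L
  }
  l
}

# full LCP array by direct pairwise comparison of sorted suffixes
oracle_lcp <- function(x) {
  os <- oracle_suffixes(x)
  n <- length(os$suf)
  c(0L, vapply(seq_len(n - 1L) + 1L, function(i) {
    oracle_lcp_pair(os$suf[i - 1L], os$suf[i])
  }, 0L))
}

# direct enhanced matching statistics of document s (with '$') against
# reference r (with '#'), straight from the definitions: factor by substring
# search, insert point by the three-case rule over sorted reference suffixes
oracle_ems <- function(s, r) {
  os <- oracle_suffixes(r)
  len <- nchar(s)
  out <- data.frame(i = seq_len(len), ell = integer(len), ip = integer(len),
                    q = integer(len), x = character(len), c = character(len),
                    stringsAsFactors = FALSE)
  for (i in seq_len(len)) {
    l <- 0L
    while (i + l <= len && grepl(substr(s, i, i + l), r, fixed = TRUE)) {
      l <- l + 1L
    }
    cc <- substr(s, i + l, i + l)
    if (l == 0L) {
      ip <- 1L
    } else {
      u <- substr(s, i, i + l - 1L)
      in_u <- which(startsWith(os$suf, u))
      below <- in_u[str_lt_vec(os$suf[in_u], paste0(u, cc))]
      ip <- if (length(below) > 0L) max(below) else min(in_u)
    }
    out$ell[i] <- l
    out$ip[i] <- ip
    out$q[i] <- os$sa[ip]
    uc <- paste0(substr(s, i, i + l - 1L), cc)
    out$x[i] <- if (str_lt(uc, os$suf[ip])) "S" else "L"
    out$c[i] <- cc
  }
  out
}

# a small random instance: collection of mutated copies plus its eCMS store
random_instance <- function(len, m, rate, seed, ref = NULL, b_p = 32L) {
  g <- generate_collection(len, m, rate, seed = seed)
  cc <- g$collection
  refstr <- if (is.null(ref)) {
    substr(cc$docs[1L], 1L, nchar(cc$docs[1L]) - 1L)
  } else ref
  idx <- reference_index(refstr, cc)
  list(cc = cc, idx = idx,
       store = ecms_store(cc, idx, b_p = b_p), ref = refstr)
}

worked_ref <- "TGATGGCACAGATACT"
worked_doc <- "GATGGCACATTGATGG"

worked_index <- function() {
  cc <- string_collection(worked_doc)
  reference_index(worked_ref, cc)
}
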