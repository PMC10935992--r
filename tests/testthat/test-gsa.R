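# The six-phase pipeline: type classification, bucketing, head ranking,
# bucket sorting, induction, and the assembled construction, each checked
# in isolation against brute force.

test_that("type classification follows the back-to-front recurrence", {
  # GATC$: position 2 (ATC$ < TC$) is S-type with an L-type predecessor,
  # hence S*; position 5 is the sentinel
  tt <- classify_types(string_collection("GATC"))[[1]]
  expect_equal(tt, c("L", "S*", "L", "L", "S*"))
  # strictly decreasing string: only the sentinel is S*
  td <- classify_types(string_collection("TGCA"))[[1]]
  expect_equal(td, c("L", "L", "L", "L", "S*"))
  set.seed(501)
  for (t in 1:15) {
    g <- generate_collection(sample(5:80, 1), 2, 0.3, seed = 13000 + t)
    types <- classify_types(g$collection)
    for (d in 1:2) {
      doc <- g$collection$docs[d]
      tv <- types[[d]]
      n <- nchar(doc)
      suf <- substring(doc, seq_len(n))
      for (i in seq_len(n - 1)) {
        expect_equal(tv[i] %in% c("S", "S*"), str_lt(suf[i], suf[i + 1]))
      }
      stars <- which(tv == "S*")
      expect_true(all(tv[stars[stars > 1] - 1L] == "L"))
      expect_equal(tv[n], "S*")
    }
  }
})

test_that("S* buckets are keyed by insert point and globally ordered", {
  set.seed(502)
  for (t in 1:10) {
    inst <- random_instance(sample(10:60, 1), sample(2:4, 1),
                            runif(1, 0, 0.3), seed = 14000 + t)
    cc <- inst$cc
    types <- classify_types(cc)
    buckets <- bucket_sstar(cc, types, inst$store)
    ips <- vapply(buckets, function(b) b$ip, 0L)
    expect_false(is.unsorted(ips, strictly = TRUE))
    # sentinels carry empty factors and land in the first bucket (rank 1)
    expect_equal(buckets[[1]]$ip, 1L)
    expect_equal(sort(buckets[[1]]$members$d), seq_len(cc$m))
    # bucket boundaries respect direct string order
    sufmax <- vapply(buckets, function(b) {
      mx <- substring(cc$docs[b$members$d], b$members$i)
      sort(mx, method = "radix")[length(mx)]
    }, "")
    sufmin <- vapply(buckets, function(b) {
      mn <- substring(cc$docs[b$members$d], b$members$i)
      sort(mn, method = "radix")[1]
    }, "")
    if (length(buckets) > 1) {
      for (k in seq_len(length(buckets) - 1)) {
        expect_true(str_lt(sufmax[k], sufmin[k + 1]) ||
                    sufmax[k] == sufmin[k + 1])
      }
    }
    # membership matches the S* set
    nstar <- sum(vapply(buckets, function(b) nrow(b$members), 0L))
    expect_equal(nstar, sum(unlist(types) == "S*"))
  }
})

test_that("partial sort of heads applies the composite key with dense ranks", {
  # two documents engineered to pin the within-group order
  cc <- string_collection(c("GATTACA", "GATTACA"))
  idx <- reference_index("GATTACA", cc)
  es <- ecms_store(cc, idx)
  ranked <- partial_sort_heads(es)
  # identical documents: head sets identical, ranks shared pairwise
  r1 <- ranked[ranked$d == 1, ]
  r2 <- ranked[ranked$d == 2, ]
  expect_equal(r1$j, r2$j)
  expect_equal(r1$prank, r2$prank)
  expect_true(all(ranked$prank > cc$m))  # terminator values stay reserved
  # at equal insert points any Smaller head precedes any Larger head, the
  # lengths ascend within S and descend within L, mismatch breaks last
  set.seed(503)
  for (t in 1:10) {
    inst <- random_instance(sample(10:60, 1), 3, runif(1, 0, 0.3),
                            seed = 15000 + t)
    rk <- partial_sort_heads(inst$store)
    o <- order(rk$prank)
    rk <- rk[o, ]
    if (nrow(rk) > 1) {
      for (r in seq_len(nrow(rk) - 1)) {
        a <- rk[r, ]; b <- rk[r + 1, ]
        if (a$prank == b$prank) {
          expect_true(a$ip == b$ip && a$x == b$x && a$ell == b$ell &&
                      a$crank == b$crank)
        } else if (a$ip == b$ip) {
          if (a$x == "S" && b$x == "S") {
            expect_true(a$ell < b$ell ||
                        (a$ell == b$ell && a$crank < b$crank))
          } else if (a$x == "L" && b$x == "L") {
            expect_true(a$ell > b$ell ||
                        (a$ell == b$ell && a$crank < b$crank))
          } else {
            expect_true(a$x == "S" && b$x == "L")
          }
        } else {
          expect_true(a$ip < b$ip)
        }
      }
    }
  }
})

test_that("the metastring lays out per-document rank runs with terminators", {
  cc <- string_collection(worked_doc)
  es <- ecms_store(cc, worked_index())
  ranked <- partial_sort_heads(es)
  meta <- build_meta_string(ranked, cc$m)
  expect_length(meta$meta, 6L)            # 5 insert-heads + 1 terminator
  expect_equal(meta$meta[6], 1L)          # terminator of document 1
  expect_equal(meta$hidx, c(1:5, 0L))
  # duplicated documents produce identical rank runs, distinct terminators
  cc2 <- string_collection(c("GATTACA", "GATTACA"))
  es2 <- ecms_store(cc2, reference_index("GATTACA", cc2))
  meta2 <- build_meta_string(partial_sort_heads(es2), 2L)
  half <- length(meta2$meta) / 2
  run1 <- meta2$meta[seq_len(half)]
  run2 <- meta2$meta[half + seq_len(half)]
  expect_equal(run1[-half], run2[-half])
  expect_equal(c(run1[half], run2[half]), c(1L, 2L))
})

test_that("head ranks agree with the full comparator on every head pair", {
  set.seed(504)
  for (t in 1:10) {
    inst <- random_instance(sample(8:50, 1), sample(2:4, 1),
                            sample(c(0, 0.02, 0.2), 1), seed = 16000 + t)
    es <- inst$store
    ranked <- partial_sort_heads(es)
    hr <- rank_heads(build_meta_string(ranked, inst$cc$m), es)
    heads <- do.call(rbind, lapply(seq_len(es$m), function(d) {
      cbind(d, es$docs[[d]]$j, hr$per_doc[[d]])
    }))
    expect_equal(sort(heads[, 3]), seq_len(nrow(heads)))  # total, dense
    pick <- cbind(sample.int(nrow(heads), 80, replace = TRUE),
                  sample.int(nrow(heads), 80, replace = TRUE))
    for (r in seq_len(nrow(pick))) {
      u <- pick[r, 1]; v <- pick[r, 2]
      if (u == v) next
      cmp <- compare_full(unname(heads[u, 1:2]), unname(heads[v, 1:2]), es)
      expect_equal(unname(cmp < 0), unname(heads[u, 3] < heads[v, 3]))
    }
  }
})

test_that("sorted S* buckets reproduce the oracle GSA restricted to S*", {
  set.seed(505)
  for (t in 1:12) {
    inst <- random_instance(sample(8:60, 1), sample(1:4, 1),
                            sample(c(0, 0.05, 0.3), 1), seed = 17000 + t)
    cc <- inst$cc; es <- inst$store
    types <- classify_types(cc)
    buckets <- bucket_sstar(cc, types, es)
    hr <- rank_heads(build_meta_string(partial_sort_heads(es), cc$m), es)
    got <- sort_sstar_buckets(buckets, es, hr)
    want <- naive_gsa(cc)
    keep <- mapply(function(d, j) types[[d]][j] == "S*",
                   want[, 1], want[, 2])
    expect_equal(unname(got), unname(want[keep, , drop = FALSE]))
  }
})

test_that("induction from the oracle-sorted S* list recovers the oracle GSA", {
  set.seed(506)
  for (t in 1:12) {
    g <- generate_collection(sample(8:60, 1), sample(1:4, 1),
                             runif(1, 0, 0.4), seed = 18000 + t)
    cc <- g$collection
    types <- classify_types(cc)
    want <- naive_gsa(cc)
    keep <- mapply(function(d, j) types[[d]][j] == "S*",
                   want[, 1], want[, 2])
    sstar <- want[keep, , drop = FALSE]
    expect_equal(unname(induce_gsa(sstar, cc, types)), unname(want))
  }
})

test_that("build_gsa equals the oracle end to end", {
  # a single document degenerates to that document's suffix array
  g1 <- build_gsa(string_collection("GATTACA"))
  expect_equal(g1$gsa[, "j"], build_suffix_array("GATTACA$"))
  expect_equal(unique(g1$gsa[, "d"]), 1L)
  # duplicated documents interleave in document order at every rank
  g2 <- build_gsa(string_collection(c("GATTACA", "GATTACA")))
  expect_equal(g2$gsa[, "d"], rep(1:2, 8))
  expect_equal(unname(g2$gsa), unname(naive_gsa(string_collection(c("GATTACA", "GATTACA")))))
  set.seed(507)
  for (t in 1:15) {
    g <- generate_collection(sample(8:100, 1), sample(1:6, 1),
                             sample(c(0, 0.01, 0.1, 0.3), 1),
                             seed = 19000 + t)
    got <- build_gsa(g$collection)
    want <- naive_gsa(g$collection)
    expect_equal(unname(got$gsa), unname(want))
    # permutation of all coordinates
    key <- paste(got$gsa[, 1], got$gsa[, 2])
    expect_equal(anyDuplicated(key), 0L)
    expect_equal(nrow(got$gsa), g$collection$N)
  }
  # an explicitly supplied reference (also present verbatim) changes nothing
  cc <- string_collection(c("GATTACA", "GATTACA", "GATCACA"))
  expect_equal(unname(build_gsa(cc, ref = "GATTACA")$gsa),
               unname(naive_gsa(cc)))
  expect_error(build_gsa(string_collection(character(0))), "at least one")
})
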