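test_that("pattern support counts all overlapping occurrences", {
  corpus <- tibble::tibble(chain_id = c("a", "b"),
                           seq = c("ACAC", "ACWY"),
                           shape = c("AAAA", "AATT"))
  res <- mine_hallmarks(corpus, min_support = 2, max_p = 1)
  ac <- res[res$pattern == "AC", ]
  expect_equal(unique(ac$support), 3)    # twice in ACAC, once in ACWY
})

test_that("mining equals the exhaustive oracle on small corpora", {
  set.seed(5)
  for (trial in 1:3) {
    corpus <- purrr::map_dfr(1:8, function(i) {
      n <- sample(10:30, 1)
      # narrow AA alphabet so patterns recur
      tibble::tibble(chain_id = paste0("c", i),
                     seq = paste(sample(c("A", "C", "D", "E"), n, TRUE),
                                 collapse = ""),
                     shape = random_shape_string(n, x_rate = 0.05))
    })
    got <- mine_hallmarks(corpus, min_support = 4, max_p = 0.05)
    want <- oracle_mine(corpus, min_support = 4, max_p = 0.05)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got_df <- as.data.frame(got)
      rownames(got_df) <- rownames(want) <- NULL
      expect_equal(got_df, want, tolerance = 1e-12)
    }
  }
})

test_that("binomial tails are exact and monotone in k", {
  # support 10, 9 modal observations, background 0.3
  direct <- sum(vapply(9:10, function(k)
    choose(10, k) * 0.3^k * 0.7^(10 - k), 0))
  expect_equal(pbinom(8, 10, 0.3, lower.tail = FALSE), direct,
               tolerance = 1e-15)
  pv <- pbinom(0:9, 10, 0.3, lower.tail = FALSE)
  expect_true(all(diff(pv) < 0))             # decreasing in k
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("min_support 1 on one sequence returns every substring", {
  corpus <- tibble::tibble(chain_id = "solo", seq = "ACDEF", shape = "AAAAA")
  res <- mine_hallmarks(corpus, min_support = 1, max_p = 1)
  n_sub <- sum(vapply(2:4, function(l) 5 - l + 1, 0))
  expect_equal(length(unique(res$pattern)), n_sub)
})

test_that("k-mer hits match a brute-force double loop", {
  set.seed(9)
  corpus <- motif_corpus()
  query <- corpus$seq[1]
  k <- 4
  got <- kmer_hits(query, corpus, k = k)
  # brute force over all substring pairs
  want <- list()
  for (i in seq_len(nrow(corpus))) {
    s <- corpus$seq[i]
    for (qs in 1:(nchar(query) - k + 1)) {
      for (ss in 1:(nchar(s) - k + 1)) {
        if (substr(query, qs, qs + k - 1) == substr(s, ss, ss + k - 1)) {
          for (d in 0:(k - 1)) {
            want[[length(want) + 1]] <- data.frame(
              query_pos = qs + d, chain_id = corpus$chain_id[i],
              subject_pos = ss + d,
              letter = substr(corpus$shape[i], ss + d, ss + d))
          }
        }
      }
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$query_pos, want$chain_id, want$subject_pos), ]
  rownames(want) <- NULL
  expect_equal(as.data.frame(got), want)
})

test_that("a query identical to a corpus chain hits its own shape letters once", {
  corpus <- tibble::tibble(chain_id = "one", seq = "ACDEFGHIKL",
                           shape = "SSRRUUVVKK")
  hits <- kmer_hits(corpus$seq, corpus, k = nchar(corpus$seq))
  expect_equal(nrow(hits), nchar(corpus$seq))
  expect_equal(hits$letter, strsplit(corpus$shape, "")[[1]])
  none <- kmer_hits("WWWWWWWW", corpus, k = 6)
  expect_equal(nrow(none), 0)
})

test_that("profile boxes count hits per position and conserve mass", {
  hits <- tibble::tibble(
    query_pos = c(rep(1L, 10), rep(2L, 3)),
    chain_id = "db",
    subject_pos = 1:13,
    letter = c(rep("A", 7), rep("T", 3), "S", "S", "X"))
  prof <- build_profile("AC", hits, top_n = 10)
  expect_equal(unname(unlist(prof[1, shape_states()])),
               c(0, 0, 0, 0, 0, 7, 3, 0))
  # X never enters boxes; total box mass equals non-X hits
  expect_equal(sum(prof[, shape_states()]), sum(hits$letter != "X"))

  empty <- build_profile("ACD", hits[0, ])
  expect_true(all(empty[, shape_states()] == 0))
})

test_that("hallmark patterns fill uncovered positions with conserved letters", {
  corpus <- motif_corpus()
  pats <- mine_hallmarks(corpus, min_support = 4, max_p = 0.05)
  expect_true("WAMD" %in% pats$pattern || "LKWA" %in% pats$pattern ||
                "KWAM" %in% pats$pattern)
  # query contains the motif but shares no k-mer at k = 12
  query <- paste0("YYYYYY", "LKWAMD", "YYYYYY")
  hits <- kmer_hits(query, corpus, k = 12)
  expect_equal(nrow(hits), 0)
  prof <- build_profile(query, hits, patterns = pats, corpus = corpus,
                        top_n = 10, flank = 5)
  motif_rows <- prof[7:12, shape_states()]
  expect_true(sum(motif_rows) > 0)
  expect_true(sum(motif_rows[, "A"]) == sum(motif_rows))  # A is conserved
})

test_that("profile alphabetization emits top/bottom bins and N for no evidence", {
  prof <- tibble::tibble(num = 1:2, aa = c("A", "C"),
                         S = c(0L, 0L), R = c(0L, 0L), U = c(0L, 0L),
                         V = c(0L, 0L), K = c(0L, 0L), A = c(10L, 0L),
                         T = c(0L, 0L), G = c(0L, 0L))
  lett <- alphabetize_profile(prof)
  expect_equal(lett$A[1], "G")                       # fraction 1 -> top bin
  expect_equal(unname(unlist(lett[1, setdiff(shape_states(), "A")])),
               rep("L", 7))                          # fraction 0 -> bottom
  expect_equal(unname(unlist(lett[2, shape_states()])), rep("N", 8))
})

test_that("hallmark libraries and external hits round-trip through TSV", {
  corpus <- motif_corpus()
  pats <- mine_hallmarks(corpus, min_support = 4, max_p = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hallmarks(pats, path)
  expect_equal(as.data.frame(read_hallmarks(path)), as.data.frame(pats),
               tolerance = 1e-12)

  hp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_pos\tletter", "1\tA", "2\tS"), hp)
  eh <- read_external_hits(hp)
  expect_equal(eh$chain_id, rep("external", 2))
  prof <- build_profile("AC", eh)
  expect_equal(prof$A[1], 1)
  expect_equal(prof$S[2], 1)
})
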