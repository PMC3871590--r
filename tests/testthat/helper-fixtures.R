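# Fixtures are built in code; oracles here are deliberately written as
# direct, slow transcriptions of the definitions, independent of the
# package's vectorized/segment-based implementations.

# random one-chain shift tibble (values rounded so text round-trips
# are exact)
random_shift_tbl <- function(n = 10, chain_id = "chainA", vac_rate = 0.2) {
  aa <- sample(amino_acids(), n, replace = TRUE)
  m <- matrix(round(runif(n * 6, 0, 100), 3), n, 6,
              dimnames = list(NULL, shift_atoms()))
  m[matrix(runif(n * 6) < vac_rate, n, 6)] <- NA_real_
  dplyr::bind_cols(
    tibble::tibble(chain_id = chain_id, num = seq_len(n), aa = aa),
    tibble::as_tibble(m))
}

random_shape_string <- function(n, alphabet = shape_states(), x_rate = 0) {
  letters <- sample(alphabet, n, replace = TRUE)
  if (x_rate > 0) letters[runif(n) < x_rate] <- "X"
  paste(letters, collapse = "")
}

# --- metric oracles -------------------------------------------------------

# per-position accuracy, straight from the definition
oracle_accuracy_total <- function(pred, ref) {
  p <- strsplit(pred, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  keep <- r != "X"
  100 * sum(p[keep] == r[keep]) / sum(keep)
}

# SOV by explicit segment enumeration (position-set based, no rle)
oracle_sov_total <- function(pred, ref, states) {
  p <- strsplit(pred, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  p[r == "X"] <- "X"
  seg_list <- function(v, s) {
    segs <- list()
    cur <- NULL
    for (i in seq_along(v)) {
      if (v[i] == s) {
        cur <- c(cur, i)
      } else if (!is.null(cur)) {
        segs[[length(segs) + 1]] <- cur
        cur <- NULL
      }
    }
    if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
    segs
  }
  num <- 0
  den <- 0
  for (s in states) {
    rs <- seg_list(r, s)
    ps <- seg_list(p, s)
    for (s1 in rs) {
      overlapped <- FALSE
      for (s2 in ps) {
        ov <- intersect(s1, s2)
        if (length(ov) == 0) next
        overlapped <- TRUE
        minov <- length(ov)
        maxov <- length(union(s1, s2))  # contiguous by construction
        delta <- min(maxov - minov, minov,
                     floor(length(s1) / 2), floor(length(s2) / 2))
        num <- num + length(s1) * (minov + delta) / maxov
        den <- den + length(s1)
      }
      if (!overlapped) den <- den + length(s1)
    }
  }
  if (den == 0) return(NA_real_)
  100 * num / den
}

# --- pattern-mining oracle ------------------------------------------------

# exhaustive substring enumeration + direct binomial tail summation
oracle_mine <- function(corpus, min_support, max_p, lengths = 2:4) {
  occ <- list()
  for (i in seq_len(nrow(corpus))) {
    s <- corpus$seq[i]
    for (len in lengths) {
      if (nchar(s) < len) next
      for (st in 1:(nchar(s) - len + 1)) {
        pat <- substr(s, st, st + len - 1)
        occ[[length(occ) + 1]] <- list(pat = pat, chain = i, start = st)
      }
    }
  }
  pats <- vapply(occ, `[[`, "", "pat")
  counts <- table(pats)
  keep_pats <- names(counts)[counts >= min_support]
  all_shapes <- strsplit(paste(corpus$shape, collapse = ""), "")[[1]]
  all_shapes <- all_shapes[all_shapes != "X"]
  bg <- table(factor(all_shapes, levels = shape_states()))
  p0 <- as.numeric(bg) / sum(bg)
  names(p0) <- shape_states()

  rows <- list()
  for (pat in keep_pats) {
    idx <- which(pats == pat)
    len <- nchar(pat)
    pos_rows <- list()
    any_cons <- FALSE
    for (j in seq_len(len)) {
      letters <- vapply(idx, function(q) {
        o <- occ[[q]]
        substr(corpus$shape[o$chain], o$start + j - 1, o$start + j - 1)
      }, "")
      letters <- letters[letters != "X"]
      if (length(letters) == 0) next
      tab <- table(factor(letters, levels = shape_states()))
      k <- max(tab)
      modal <- shape_states()[which.max(tab)]
      n <- length(letters)
      # direct tail summation, independent of pbinom
      pv <- sum(vapply(k:n, function(kk)
        choose(n, kk) * p0[[modal]]^kk * (1 - p0[[modal]])^(n - kk), 0))
      cons <- pv <= max_p
      if (cons) any_cons <- TRUE
      pos_rows[[length(pos_rows) + 1]] <-
        data.frame(pattern = pat, length = len,
                   support = as.integer(counts[[pat]]), position = j,
                   letter = modal, n = n, k = as.integer(k), p_value = pv,
                   conserved = cons)
    }
    if (any_cons) rows <- c(rows, pos_rows)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$pattern, out$position), ]
}

# --- CRF enumeration oracle ----------------------------------------------

# brute force over all K^L paths
oracle_crf_enumerate <- function(emis, trans) {
  L <- nrow(emis)
  K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(1:K), L)))
  scores <- numeric(nrow(paths))
  for (t in 1:L) scores <- scores + emis[t, ][paths[, t]]
  if (L > 1) {
    for (t in 2:L) scores <- scores + trans[cbind(paths[, t - 1], paths[, t])]
  }
  m <- max(scores)
  list(logZ = m + log(sum(exp(scores - m))),
       viterbi_score = max(scores),
       viterbi_path = paths[which.max(scores), ])
}

# small annotated corpus with repeated motifs for profile tests
motif_corpus <- function(n_chains = 6, seed = 42) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_chains), function(i) {
    # shared helix motif with conserved A block + random tails
    tail1 <- paste(sample(amino_acids(), 6, TRUE), collapse = "")
    tail2 <- paste(sample(amino_acids(), 6, TRUE), collapse = "")
    seq <- paste0(tail1, "LKWAMD", tail2)
    shape <- paste0(random_shape_string(6, c("S", "R", "T")),
                    "AAAAAA",
                    random_shape_string(6, c("S", "R", "T")))
    tibble::tibble(chain_id = paste0("m", i), seq = seq, shape = shape)
  })
}
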