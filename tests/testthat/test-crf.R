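make_letters <- function(n, seed = 1) {
  set.seed(seed)
  sl <- tibble::as_tibble(matrix(sample(shift_letters()[1:10], n * 6, TRUE),
                                 n, 6, dimnames = list(NULL, shift_atoms())))
  pl <- tibble::as_tibble(matrix(sample(shift_letters()[1:10], n * 8, TRUE),
                                 n, 8, dimnames = list(NULL, shape_states())))
  list(sl = sl, pl = pl)
}

test_that("featurization emits 14 features per offset with boundary tokens", {
  lt <- make_letters(5)
  f0 <- crf_featurize(lt$sl, lt$pl, window = 0)
  expect_equal(dim(f0), c(5, 14))
  f2 <- crf_featurize(lt$sl, lt$pl, window = 2)
  expect_equal(dim(f2), c(5, 14 * 5))
  # offsets -2,-1 at position 1 are boundary ids; the boundary letter is
  # the 12th letter of each slot's id block
  nl <- 12
  slot_letter <- function(id) (id - 1) %% nl + 1
  # slots are ordered (feature, offset); offsets -2 and -1 are the first
  # two slots of each feature block
  first_feature_ids <- f2[1, 1:5]
  expect_equal(slot_letter(first_feature_ids[1]), nl)  # offset -2
  expect_equal(slot_letter(first_feature_ids[2]), nl)  # offset -1
  expect_false(slot_letter(first_feature_ids[3]) == nl)  # offset 0 is real
  expect_error(crf_featurize(lt$sl, lt$pl[1:3, ], window = 1),
               "lengths differ")
})

test_that("forward-backward and Viterbi match exhaustive enumeration", {
  set.seed(33)
  for (trial in 1:25) {
    L <- sample(2:6, 1)
    emis <- matrix(rnorm(L * 8), L, 8)
    trans <- matrix(rnorm(64), 8, 8)
    want <- oracle_crf_enumerate(emis, trans)
    fb <- crf_forward_backward(emis, trans)
    vit <- crf_viterbi(emis, trans)
    expect_equal(fb$logZ, want$logZ, tolerance = 1e-10)
    expect_equal(vit$score, want$viterbi_score, tolerance = 1e-10)
    expect_equal(vit$path, unname(want$viterbi_path))
    expect_equal(rowSums(fb$marginals), rep(1, L), tolerance = 1e-9)
  }
})

test_that("Viterbi probability dominates randomly sampled paths", {
  set.seed(44)
  L <- 20
  emis <- matrix(rnorm(L * 8), L, 8)
  trans <- matrix(rnorm(64), 8, 8)
  vit <- crf_viterbi(emis, trans)
  path_score <- function(p) {
    s <- sum(emis[cbind(1:L, p)])
    s + sum(trans[cbind(p[-L], p[-1])])
  }
  rand <- replicate(1000, path_score(sample.int(8, L, TRUE)))
  expect_true(all(vit$score >= rand))
})

test_that("with zero transitions Viterbi is the per-position argmax", {
  set.seed(55)
  emis <- matrix(rnorm(15 * 8), 15, 8)
  vit <- crf_viterbi(emis, matrix(0, 8, 8))
  expect_equal(vit$path, unname(max.col(emis)))
})

test_that("a separable toy corpus is learned to 100% and training is deterministic", {
  # HA letter uniquely determines the label
  set.seed(66)
  lab2letter <- setNames(shift_letters()[1:8], shape_states())
  feats <- list()
  labels <- character()
  for (i in 1:6) {
    y <- random_shape_string(30)
    sl <- tibble::as_tibble(matrix("N", 30, 6,
                                   dimnames = list(NULL, shift_atoms())))
    sl$HA <- unname(lab2letter[strsplit(y, "")[[1]]])
    feats[[i]] <- crf_featurize(sl, NULL, window = 1)
    labels[i] <- y
  }
  m1 <- shape_crf(feats, labels, l2 = 0.1, max_iter = 100)
  m2 <- shape_crf(feats, labels, l2 = 0.1, max_iter = 100)
  expect_identical(m1$weights, m2$weights)
  pred <- predict(m1, feats[[1]])
  expect_equal(attr(pred, "shape"), labels[1])
  # objective improved and marginals are proper
  expect_lt(m1$objective, m1$trace[1])
  marg <- as.matrix(pred[, paste0("P_", shape_states())])
  expect_equal(rowSums(marg), rep(1, 30), tolerance = 1e-9)
})

test_that("X runs split training sequences and all-X chains are skipped", {
  lt <- make_letters(12, seed = 8)
  f <- crf_featurize(lt$sl, lt$pl, window = 1)
  lab <- paste0("AAAA", "XXXX", "TTTT")
  expect_silent(m <- shape_crf(list(f), lab, max_iter = 10))
  expect_equal(m$n_sequences, 2)
  expect_equal(m$n_positions, 8)
  expect_warning(
    expect_error(shape_crf(list(f), strrep("X", 12), max_iter = 5),
                 "no trainable"),
    "all-X")
})

test_that("models serialize to JSON and reload bit-stably", {
  lt <- make_letters(10, seed = 9)
  f <- crf_featurize(lt$sl, lt$pl, window = 1)
  m <- shape_crf(list(f), random_shape_string(10), max_iter = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_crf_model(m, path)
  back <- read_crf_model(path)
  expect_identical(back$weights, m$weights)
  expect_identical(back$trans, m$trans)
  expect_equal(back$window, m$window)
  p1 <- predict(m, f)
  p2 <- predict(back, f)
  expect_identical(p1, p2)
  # template mismatch is refused
  f2 <- crf_featurize(lt$sl, lt$pl, window = 2)
  expect_error(predict(m, f2), "template")
})

test_that("tidy and glance expose the fit", {
  lt <- make_letters(10, seed = 10)
  f <- crf_featurize(lt$sl, lt$pl, window = 1)
  m <- shape_crf(list(f), random_shape_string(10), max_iter = 10)
  td <- tidy(m)
  expect_equal(nrow(td), m$n_feature_ids * 8 + 64)
  expect_true(all(c("emission", "transition") %in% td$type))
  g <- glance(m)
  expect_equal(g$n_positions, 10)
  expect_equal(g$window, 1)
})
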