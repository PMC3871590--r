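test_that("accuracy counts per class and excludes reference X", {
  acc <- shape_accuracy("AAAT", "AAAS")
  expect_equal(acc$accuracy[acc$state == "total"], 75)
  expect_equal(acc$accuracy[acc$state == "A"], 100)
  expect_equal(acc$accuracy[acc$state == "S"], 0)
  expect_true(is.na(acc$accuracy[acc$state == "G"]))

  perfect <- shape_accuracy("SRUVAKTG", "SRUVAKTG")
  expect_true(all(perfect$accuracy[!is.na(perfect$accuracy)] == 100))

  xacc <- shape_accuracy("AAAA", "AXAX")
  expect_equal(xacc$m[xacc$state == "total"], 2)
  expect_equal(xacc$accuracy[xacc$state == "total"], 100)
  expect_error(shape_accuracy("AA", "AAA"), "lengths differ")
})

test_that("SOV anchors: identity 100, disjoint 0, 1-residue shift 100", {
  expect_equal(shape_sov("AAAASSSS", "AAAASSSS")$sov[9], 100)
  s <- shape_sov("AAASSSSS", "AAAASSSS")
  expect_equal(s$sov[s$state == "A"], 100)
  expect_equal(s$sov[s$state == "S"], 100)
  expect_equal(s$sov[s$state == "total"], 100)
  disj <- shape_sov("TTTTAAAA", "AAAATTTT")
  expect_equal(disj$sov[disj$state == "A"], 0)
  expect_equal(disj$sov[disj$state == "T"], 0)
})

test_that("accuracy and SOV match brute-force oracles on random pairs", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    if (i %% 2 == 0) {
      pred <- random_shape_string(n)
      ref <- random_shape_string(n, x_rate = 0.1)
      states <- shape_states()
    } else {
      pred <- random_shape_string(n, alphabet = c("S", "H", "T"))
      ref <- random_shape_string(n, alphabet = c("S", "H", "T"),
                                 x_rate = 0.1)
      states <- c("S", "H", "T")
    }
    acc <- shape_accuracy(pred, ref, states)
    expect_equal(acc$accuracy[acc$state == "total"],
                 oracle_accuracy_total(pred, ref))
    sov <- shape_sov(pred, ref, states)
    expect_equal(sov$sov[sov$state == "total"],
                 oracle_sov_total(pred, ref, states))
  }
})

test_that("SOV stays within [0, 100]", {
  set.seed(78)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    s <- shape_sov(random_shape_string(n), random_shape_string(n))
    vals <- s$sov[!is.na(s$sov)]
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("three-state accuracy dominates eight-state accuracy", {
  set.seed(79)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    pred <- random_shape_string(n)
    ref <- random_shape_string(n, x_rate = 0.05)
    g <- glance(evaluate_prediction(pred, ref))
    expect_gte(g$s3, g$s8)
  }
})

test_that("evaluation reports populate all states and both granularities", {
  ev <- evaluate_prediction("SRUVAKTGSRUVAKTG", "SRUVAKTGAAAAAAAA")
  td <- tidy(ev)
  expect_setequal(unique(td$states), c(8, 3))
  expect_true(all(shape_states() %in% td$state[td$states == 8]))
  g <- glance(ev)
  expect_true(all(c("s8", "sov8", "s3", "sov3") %in% names(g)))
  id <- evaluate_prediction("SSAAKK", "SSAAKK")
  expect_equal(unname(unlist(glance(id)[, 1:4])), rep(100, 4))
})

test_that("bootstrap is deterministic, degenerate on perfect input, and shrinks with n", {
  refs <- replicate(8, random_shape_string(30))
  b0 <- bootstrap_metric(refs, refs, metrics = "s8", reps = 50, seed = 4)
  expect_equal(b0$mean, 100)
  expect_equal(b0$se, 0)

  set.seed(80)
  preds <- vapply(refs, function(r) {
    v <- strsplit(r, "")[[1]]
    flip <- runif(30) < 0.3
    v[flip] <- sample(shape_states(), sum(flip), TRUE)
    paste(v, collapse = "")
  }, "")
  b1 <- bootstrap_metric(preds, refs, reps = 400, seed = 9)
  b2 <- bootstrap_metric(preds, refs, reps = 400, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$se > 0))
  # quadrupling the target list shrinks the SE roughly by half
  b4 <- bootstrap_metric(rep(preds, 4), rep(refs, 4),
                         metrics = "s8", reps = 2000, seed = 9)
  ratio <- b4$se / b1$se[b1$metric == "s8"]
  expect_lt(ratio, 0.75)
  expect_gt(ratio, 0.3)
  expect_error(bootstrap_metric(preds[1], refs[1]), "at least 2")
})
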