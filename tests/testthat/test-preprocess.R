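test_that("scale fitting takes per-(aa, atom) extremes and skips vacancies", {
  corp <- tibble::tibble(
    chain_id = "c1", num = 1:4, aa = c("A", "A", "A", "G"),
    HA = c(4.0, NA, 4.5, 3.9), H = NA_real_, N = NA_real_,
    CA = c(50.0, 54.0, 52.0, 45.0), CB = NA_real_, C = NA_real_)
  tab <- fit_scale_table(corp)
  a_ca <- tab[tab$aa == "A" & tab$atom == "CA", ]
  expect_equal(c(a_ca$x_min, a_ca$x_max), c(50, 54))
  a_ha <- tab[tab$aa == "A" & tab$atom == "HA", ]
  expect_equal(a_ha$n_obs, 2)            # NA not counted
  expect_equal(c(a_ha$x_min, a_ha$x_max), c(4.0, 4.5))
  g_ca <- tab[tab$aa == "G" & tab$atom == "CA", ]
  expect_true(g_ca$degenerate)           # single observation
  expect_equal(g_ca$x_min, g_ca$x_max)
})

test_that("normalization is the clipped linear transform", {
  tab <- fit_scale_table(tibble::tibble(
    chain_id = "c", num = 1:2, aa = "A",
    HA = c(0, 10), H = NA_real_, N = NA_real_, CA = NA_real_,
    CB = NA_real_, C = NA_real_))
  expect_equal(normalize_shift(5, "A", "HA", tab), 0.5)
  expect_equal(normalize_shift(12, "A", "HA", tab), 1)   # clipped high
  expect_equal(normalize_shift(-3, "A", "HA", tab), 0)   # clipped low
  expect_equal(normalize_shift(0, "A", "HA", tab), 0)    # x == x_min
  expect_true(is.na(normalize_shift(NA, "A", "HA", tab)))
  expect_error(normalize_shift(5, "G", "CA", tab), "absent or degenerate")
  expect_warning(
    out <- normalize_shift(5, "G", "CA", tab, strict = FALSE),
    "vacancy")
  expect_true(is.na(out))
})

test_that("the ten-bin alphabet maps ascending bins to the listed letters", {
  expect_equal(alphabetize(0.05), "L")
  expect_equal(alphabetize(1.0), "G")
  expect_equal(alphabetize(NA), "N")
  # one letter per bin, in order
  expect_equal(alphabetize(seq(0.05, 0.95, by = 0.1)),
               c("L", "A", "D", "C", "Q", "M", "V", "W", "P", "G"))
  # monotone step function over a fine grid
  v <- seq(0, 1, by = 0.001)
  idx <- match(alphabetize(v), shift_letters())
  expect_true(all(diff(idx) >= 0))
  expect_error(alphabetize(1.2), "normalize first")
})

test_that("a corpus covering all combinations yields exactly 120 entries and no clipping on itself", {
  set.seed(11)
  corp <- purrr::map_dfr(1:30, function(i)
    random_shift_tbl(20, sprintf("c%d", i), vac_rate = 0.1))
  corp$aa <- rep(amino_acids(), nrow(corp) / 20)
  tab <- fit_scale_table(corp)
  expect_equal(nrow(tab), 120)
  expect_true(all(tab$x_min <= tab$x_max))
  # normalizing the training corpus itself never leaves [0,1] and never clips
  for (a in shift_atoms()) {
    v <- normalize_shift(corp[[a]], corp$aa, a, tab, strict = FALSE)
    live <- !is.na(v)
    expect_true(all(v[live] >= 0 & v[live] <= 1))
  }
})

test_that("record alphabetization composes normalize and binning over 6 atoms", {
  rec <- tibble::tibble(chain_id = "c", num = 1:2, aa = "A",
                        HA = c(0, 10), H = c(1, 3), N = c(100, 120),
                        CA = c(50, 60), CB = c(20, 40), C = c(170, 180))
  tab <- fit_scale_table(rec)
  lett <- alphabetize_shifts(rec, tab)
  expect_equal(dim(lett), c(2, 9))
  # extremes map to first and last letters
  expect_equal(unname(unlist(lett[1, shift_atoms()])), rep("L", 6))
  expect_equal(unname(unlist(lett[2, shift_atoms()])), rep("G", 6))

  vac <- rec
  vac[, shift_atoms()] <- NA_real_
  lett2 <- alphabetize_shifts(vac, tab)
  expect_true(all(lett2[, shift_atoms()] == "N"))
})

test_that("scale tables round-trip through TSV", {
  set.seed(3)
  tab <- fit_scale_table(random_shift_tbl(50, vac_rate = 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scale_table(tab, path)
  back <- read_scale_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab[, names(back)]))
  expect_error(read_scale_table(system.file("extdata", "torsion_regions.tsv",
                                            package = "shapecrf")),
               "not a scale-table")
})
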