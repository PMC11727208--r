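# minimal annotations object for profile tests
fake_annotations <- function(df, fraction = "neutral_sialylated") {
  tab <- data.frame(
    peak_id = seq_len(nrow(df)), mz = 2000, intensity = df$intensity,
    snr = 10, assigned = TRUE, composition = df$composition,
    ion_mz = 2000, error_da = 0, n_candidates = 1L,
    stringsAsFactors = FALSE)
  cls <- lapply(df$composition, function(s) classify(parse_composition(s)))
  tab$category <- vapply(cls, `[[`, character(1), "category")
  tab$antennarity <- vapply(cls, `[[`, integer(1), "antennarity")
  tab$bisect_candidate <- vapply(cls, `[[`, logical(1), "bisect_candidate")
  tab$core_fucosylated <- vapply(cls, `[[`, logical(1), "core_fucosylated")
  tab$sialylation_count <- vapply(cls, `[[`, integer(1), "sialylation_count")
  tab$sulfation_count <- vapply(cls, `[[`, integer(1), "sulfation_count")
  structure(list(table = tab, candidates = list(), polarity = "positive",
                 fraction = fraction, range = c(1000, 6000),
                 tolerance_da = 0.5, satellites = NULL),
            class = "glycan_annotations")
}

test_that("class profiles are TIC-normalized fractions of assigned signal", {
  one <- fake_annotations(data.frame(composition = "Hex5HexNAc2",
                                     intensity = 7))
  pr <- class_profile(one, "s1", "normal")
  expect_equal(pr$oligomannose, 1.0)
  expect_equal(pr$sialylated, 0)

  two <- fake_annotations(data.frame(
    composition = c("Hex5HexNAc4Fuc1NeuAc1", "Hex5HexNAc4Fuc1"),
    intensity = c(5, 5)))
  pr <- class_profile(two, "s2", "tumor")
  expect_equal(pr$sialylated, 0.5)
  expect_equal(pr$complex, 1.0)

  # the four structural categories partition the assigned intensity
  mix <- fake_annotations(data.frame(
    composition = c("Hex5HexNAc2", "Hex4HexNAc2", "Hex5HexNAc3",
                    "Hex5HexNAc4Fuc1", "Hex6HexNAc5Fuc1NeuAc1"),
    intensity = c(3, 1, 2, 8, 4)))
  pr <- class_profile(mix, "s3", "normal")
  expect_equal(pr$oligomannose + pr$paucimannose + pr$hybrid + pr$complex,
               1, tolerance = 1e-9)
  expect_equal(pr$branched, 4 / 18)

  empty <- fake_annotations(data.frame(composition = "Hex5HexNAc2",
                                       intensity = 1))
  empty$table$assigned <- FALSE
  expect_error(class_profile(empty), "no assigned peaks")
})

test_that("unpaired t matches the hand-computed pooled-variance form", {
  # x = {1,2,3}, y = {2,3,4}: pooled s^2 = 1, t = -1/sqrt(2/3)
  tt <- ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_false(tt$significant)

  # identical groups with spread: t = 0, p = 1
  tt <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
})

test_that("unpaired t is antisymmetric under group swap", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(5, 0.5, 0.05); y <- rnorm(5, 0.55, 0.05)
    a <- ttest_unpaired(x, y); b <- ttest_unpaired(y, x)
    expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate unpaired inputs are refused or exact", {
  expect_error(ttest_unpaired(c(1, 1), c(1, 1)), "degenerate")
  expect_warning(tt <- ttest_unpaired(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(tt$p_value, 0)
  expect_true(tt$significant)
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")
})

toy_matrix <- function(normal, tumor) {
  n <- length(normal)
  rpkm <- matrix(c(normal, tumor), nrow = 1,
                 dimnames = list("G", c(sprintf("N%d", 1:n),
                                        sprintf("T%d", 1:n))))
  expression_matrix(rpkm, data.frame(patient = sprintf("P%d", 1:n),
                                     normal = sprintf("N%d", 1:n),
                                     tumor = sprintf("T%d", 1:n)))
}

test_that("paired t matches the closed form on a 3-pair toy table", {
  # differences {1, 2, 3}: t = mean/sd * sqrt(3) = 2 sqrt(3)
  m <- toy_matrix(c(10, 20, 30), c(11, 22, 33))
  tt <- ttest_paired(m, "G")
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
})

test_that("paired t is symmetric and shift-invariant", {
  # zero-mean symmetric differences +/- d give t = 0, p = 1
  m <- toy_matrix(c(10, 20), c(12, 18))
  tt <- ttest_paired(m, "G")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  # adding a constant to both members of every pair changes nothing
  m1 <- toy_matrix(c(10, 20, 30), c(12, 25, 31))
  m2 <- toy_matrix(c(10, 20, 30) + 100, c(12, 25, 31) + 100)
  expect_equal(ttest_paired(m1, "G")$statistic,
               ttest_paired(m2, "G")$statistic, tolerance = 1e-12)
})

test_that("degenerate paired inputs are refused or exact", {
  expect_error(ttest_paired(toy_matrix(c(1, 2), c(1, 2)), "G"),
               "degenerate")
  expect_warning(tt <- ttest_paired(toy_matrix(c(1, 2), c(3, 4)), "G"),
                 "identical")
  expect_equal(tt$p_value, 0)
  expect_error(ttest_paired(toy_matrix(c(1, 2), c(2, 3)), "missing"),
               "not in matrix")
})

test_that("expression matrix validates pairing and non-negativity", {
  rpkm <- matrix(1, 1, 2, dimnames = list("G", c("a", "b")))
  expect_error(expression_matrix(rpkm - 2,
                                 data.frame(patient = "P", normal = "a",
                                            tumor = "b")),
               "non-negative")
  expect_error(expression_matrix(rpkm,
                                 data.frame(patient = c("P", "P"),
                                            normal = c("a", "a"),
                                            tumor = c("b", "b"))),
               "exactly one")
  expect_error(expression_matrix(rpkm,
                                 data.frame(patient = "P", normal = "a",
                                            tumor = "zzz")),
               "missing samples")
})

test_that("planted cohort effects surface as group differences", {
  co <- simulate_cohort(cohort_sim_config(n_pairs = 5, seed = 21))
  profiles <- do.call(rbind, lapply(names(co$samples), function(p) {
    rbind(
      class_profile(list(
        annotate_spectrum(co$samples[[p]]$normal$neutral$spectrum),
        annotate_spectrum(co$samples[[p]]$normal$sulfated$spectrum)),
        p, "normal"),
      class_profile(list(
        annotate_spectrum(co$samples[[p]]$tumor$neutral$spectrum),
        annotate_spectrum(co$samples[[p]]$tumor$sulfated$spectrum)),
        p, "tumor"))
  }))
  res <- compare_class_profiles(profiles)
  expect_gt(res$t[res$class == "branched"], 0)
  expect_lt(res$t[res$class == "di_sulfated"], 0)
})

test_that("group-level branched direction is recovered across replicates", {
  hits <- 0L
  for (s in 1:10) {
    co <- simulate_cohort(cohort_sim_config(n_pairs = 5, seed = 300 + s))
    profiles <- do.call(rbind, lapply(names(co$samples), function(p) {
      rbind(
        class_profile(list(
          annotate_spectrum(co$samples[[p]]$normal$neutral$spectrum),
          annotate_spectrum(co$samples[[p]]$normal$sulfated$spectrum)),
          p, "normal"),
        class_profile(list(
          annotate_spectrum(co$samples[[p]]$tumor$neutral$spectrum),
          annotate_spectrum(co$samples[[p]]$tumor$sulfated$spectrum)),
          p, "tumor"))
    }))
    mt <- mean(profiles$branched[profiles$group == "tumor"])
    mn <- mean(profiles$branched[profiles$group == "normal"])
    if (mt > mn) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.9)
})
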