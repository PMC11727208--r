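write_peaklist <- function(lines, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("peak lists are read, sorted, and validated", {
  p <- write_peaklist(c("mz,intensity,snr", "2000,5,10", "1500,3,4",
                        "1800,1,2.5"))
  sp <- read_peaklist(p, "positive", "neutral_sialylated")
  expect_s3_class(sp, "glycan_spectrum")
  expect_equal(sp$peaks$mz, c(1500, 1800, 2000))
  expect_equal(sp$peaks$intensity, c(3, 1, 5))

  bad <- write_peaklist(c("mz,intensity", "1500,2", "abc,1.0"))
  expect_error(read_peaklist(bad, "positive", "neutral_sialylated"),
               "line 3")
  empty <- write_peaklist("mz,intensity")
  expect_error(read_peaklist(empty, "positive", "neutral_sialylated"),
               "empty")
  # tab-delimited input is auto-detected
  tsv <- write_peaklist(c("mz\tintensity\tsnr", "1500\t2\t3"))
  expect_equal(read_peaklist(tsv, "positive",
                             "neutral_sialylated")$peaks$mz, 1500)
})

test_that("missing snr is imputed from median intensity with a warning", {
  p <- write_peaklist(c("mz,intensity", "1500,10", "1600,20", "1700,40"))
  expect_warning(sp <- read_peaklist(p, "positive", "neutral_sialylated"),
                 "imputing")
  expect_equal(sp$peaks$snr, c(10, 20, 40) / 20)
})

test_that("S/N filtering keeps the threshold and the range", {
  sp <- glycan_spectrum(data.frame(mz = c(900, 1500, 1600, 1700, 6500),
                                   intensity = 1,
                                   snr = c(10, 2.0, 1.99, 50, 10)),
                        "positive", "neutral_sialylated")
  f <- filter_peaks(sp, min_snr = 2.0)
  expect_equal(f$peaks$mz, c(1500, 1700))  # snr 2.0 retained, 1.99 dropped
  empty <- filter_peaks(glycan_spectrum(
    data.frame(mz = numeric(), intensity = numeric(), snr = numeric()),
    "positive", "neutral_sialylated"))
  expect_equal(nrow(empty$peaks), 0)
})

test_that("enumeration finds the expected compositions at printed targets", {
  got <- enumerate_compositions(1579.8, "positive", 0.5)
  expect_true("Hex5HexNAc2" %in% got$composition)
  got <- enumerate_compositions(2966.5, "positive", 0.5)
  expect_true("Hex5HexNAc4Fuc1NeuAc2" %in% got$composition)
  got <- enumerate_compositions(2286.07, "negative", 0.5)
  expect_equal(got$composition[1], "Hex5HexNAc4Fuc1Sulf1")
})

test_that("enumeration agrees with the brute-force oracle", {
  set.seed(101)
  for (pol in c("positive", "negative")) {
    targets <- runif(15, 1000, 6000)
    for (t in targets) {
      got <- enumerate_compositions(t, pol, 0.5)
      want <- oracle_enumerate(t, pol, 0.5)
      expect_identical(comp_key(got), comp_key(want))
    }
  }
})

test_that("annotation assigns the oligomannose series and flags orphans", {
  oligo <- sprintf("Hex%dHexNAc2", 5:9)
  mz <- vapply(oligo, function(s) ion_mz(parse_composition(s), "positive"),
               numeric(1))
  sp <- glycan_spectrum(data.frame(mz = c(mz, 1001.0),
                                   intensity = c(5:1 * 10, 3),
                                   snr = 10),
                        "positive", "neutral_sialylated")
  ann <- annotate_spectrum(sp)
  expect_equal(sum(ann$table$assigned), 5)
  expect_identical(ann$table$composition[ann$table$assigned],
                   unname(oligo))
  expect_false(ann$table$assigned[ann$table$mz == 1001.0])
  expect_true(all(ann$table$category[ann$table$assigned] == "oligomannose"))
  # no annotation error ever exceeds the tolerance
  expect_true(all(abs(ann$table$error_da[ann$table$assigned]) <= 0.5))
})

test_that("fraction and polarity must be consistent", {
  sp <- glycan_spectrum(data.frame(mz = 2286.07, intensity = 1, snr = 10),
                        "positive", "sulfated")
  expect_error(annotate_spectrum(sp), "mismatch")
})

test_that("satellite spacings are linked without touching assignments", {
  sp <- glycan_spectrum(data.frame(mz = c(2272.05, 2286.07, 2373.99, 3000),
                                   intensity = c(2, 10, 3, 1), snr = 10),
                        "negative", "sulfated")
  ann <- flag_satellites(annotate_spectrum(sp))
  sat <- ann$satellites
  under <- sat[sat$label == "under_permethylation", ]
  expect_equal(nrow(under), 1)
  expect_equal(ann$table$mz[ann$table$peak_id == under$peak_id], 2272.05)
  di <- sat[sat$label == "di_sulfation_candidate", ]
  expect_equal(nrow(di), 1)
  expect_equal(ann$table$mz[ann$table$peak_id == di$peak_id], 2373.99)
  # the isolated peak is linked to nothing
  expect_false(4 %in% c(sat$peak_id, sat$parent_id))
  # rank-1 assignment of the parent is unchanged by flagging
  plain <- annotate_spectrum(sp)
  expect_identical(ann$table$composition, plain$table$composition)
})

test_that("annotation reports are deterministic byte for byte", {
  sim <- simulate_spectrum(spectrum_sim_config(fraction = "sulfated",
                                               seed = 11))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotations(flag_satellites(annotate_spectrum(sim$spectrum)), f1)
  sim2 <- simulate_spectrum(spectrum_sim_config(fraction = "sulfated",
                                                seed = 11))
  write_annotations(flag_satellites(annotate_spectrum(sim2$spectrum)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1)
})
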