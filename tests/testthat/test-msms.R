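test_that("topology strings parse to the declared composition", {
  topo <- sulfo_biantennary_topology()
  expect_equal(nrow(topo$nodes), 10)
  expect_identical(format(topology_composition(topo)),
                   "Hex5HexNAc4Fuc1Sulf1")
  expect_equal(sum(topo$nodes$parent == 0), 1)  # exactly one root
  expect_identical(topo$nodes$class[1], "hexnac")
  expect_error(parse_topology("GlcNAc(Xyl)"), "unknown residue")
  expect_error(parse_topology("GlcNAc(Man"), "unbalanced|expected")
  expect_error(parse_topology("GlcNAc[3]"), "malformed sulfo")
})

test_that("single-cleavage enumeration yields four ions per bond", {
  topo <- sulfo_biantennary_topology()
  fr <- enumerate_glycosidic_fragments(topo, "negative", max_cleavages = 1)
  E <- nrow(topo$nodes) - 1
  expect_equal(nrow(fr), 4 * E)
  expect_equal(sort(unique(fr$type)), c("B", "C", "Y", "Z"))
  expect_true(all(fr$mz[fr$observable] > 0))
  # in negative mode only sulfate-retaining fragments ionize
  expect_true(all(fr$contains_sulfo[fr$observable & fr$type %in% c("B", "C")]))
})

test_that("fragment conventions reproduce the printed MS/MS ions", {
  topo <- sulfo_biantennary_topology()
  fr <- enumerate_glycosidic_fragments(topo, "negative", max_cleavages = 2)
  mz <- fr$mz[fr$observable]
  # core fucosylation: B-type loss of reducing GlcNAc+Fuc
  expect_true(any(abs(mz - 1834) <= 1.0))
  # sequential Y losses of the non-sulfo antenna: terminal Gal, then GlcNAc
  expect_true(any(abs(mz - 2067) <= 1.0))
  expect_true(any(abs(mz - 1822) <= 1.0))
})

test_that("positive B and Y ions of one cleavage reconstruct the precursor", {
  topo <- sulfo_biantennary_topology()
  fr <- enumerate_glycosidic_fragments(topo, "positive", max_cleavages = 1)
  prec <- attr(fr, "precursor_mz")
  mc_sod <- 22.98977 - 1.00783
  for (e in unique(fr$edges[fr$type == "B"])) {
    b <- fr[fr$type == "B" & fr$edges == e, ]
    y <- fr[fr$type == "Y" & fr$edges == e, ]
    # undo the end-group bookkeeping: B carries +15.0229 and a sodiation,
    # Y lost the B residues plus 14.0157 (and the sulfate's sodium if the
    # sulfate left with the B side)
    sulfo_na <- if (b$contains_sulfo) mc_sod else 0
    recon <- b$mz - 15.0229 - mc_sod + y$mz + 14.0157 + sulfo_na
    expect_equal(recon, prec, tolerance = 1e-2)
  }
})

test_that("diagnostic table matches independent recomputation", {
  dt <- diagnostic_ions()
  # sulfate anion HSO4-
  hso4 <- oracle_formula_mass(H = 1, O = 4, S = 1)
  expect_equal(dt$mz[dt$label == "HSO4-"], hso4, tolerance = 0.05)
  expect_equal(round(dt$mz[dt$label == "HSO4-"]), 97)
  # B-type sulfo-Gal: sulfated hexose residue + B terminus - 2H
  sulfo_gal <- oracle_res[["hex"]] + oracle_res[["sulfo"]]
  expect_equal(dt$mz[dt$label == "B_sulfoGal"],
               sulfo_gal + 15.0229 - 2 * oracle_atomic[["H"]],
               tolerance = 0.05)
  expect_lt(abs(dt$mz[dt$label == "B_sulfoGal"] - 283), 1.0)
  expect_lt(abs(dt$mz[dt$label == "B_sulfoLacNAc"] - 528), 1.0)
})

test_that("the sulfo-linkage decision chain follows its evidence", {
  full <- c(96.96, 528.2, 283.0, 153.0, 253.1, 181.1)
  v <- assign_sulfo_linkage(full, "negative")
  expect_true(v$sulfate_present)
  expect_true(v$sulfo_on_LacNAc)
  expect_equal(v$sulfo_position, "terminal_Gal")
  expect_equal(v$linkage, "3-O-Gal")

  # sulfate alone licenses nothing about position or linkage
  v <- assign_sulfo_linkage(96.96, "negative")
  expect_true(v$sulfate_present)
  expect_false(v$sulfo_on_LacNAc)
  expect_equal(v$sulfo_position, "indeterminate")
  expect_equal(v$linkage, "indeterminate")

  # cross-ring ions without the sulfate anion do not license the linkage
  v <- assign_sulfo_linkage(c(153.0, 181.1), "negative")
  expect_equal(v$linkage, "indeterminate")

  v <- assign_sulfo_linkage(numeric(0), "negative")
  expect_false(v$sulfate_present)
  expect_equal(v$linkage, "indeterminate")

  expect_warning(v <- assign_sulfo_linkage(full, "positive"),
                 "negative-mode")
  expect_false(v$sulfate_present)
})

test_that("MS/MS annotation matches peaks, flags diagnostics and covers bonds", {
  topo <- sulfo_biantennary_topology()
  peaks <- c(96.96, 153.0, 181.1, 253.1, 283.0, 528.2, 1834.8, 2067.9,
             1822.8)
  res <- annotate_msms(topo, peaks, "negative", precursor_mz = 2286.1)
  expect_true(all(c(283.0, 528.2, 1834.8, 2067.9, 1822.8) %in%
                    res$matches$peak_mz))
  expect_true(all(abs(res$matches$error_da) <= 0.5))
  expect_true("HSO4-" %in% res$diagnostics$label)
  expect_equal(res$verdict$linkage, "3-O-Gal")
  expect_gt(res$coverage, 0)
  expect_lte(res$coverage, 1)

  # positive-mode sodiated LacNAc B ion
  pos <- annotate_msms(topo, 486.2, "positive")
  expect_equal(nrow(pos$matches), 1)
  expect_identical(pos$matches$composition, "Hex1HexNAc1")

  none <- annotate_msms(topo, numeric(0), "negative")
  expect_equal(none$coverage, 0)
  expect_error(annotate_msms(topo, peaks, "negative", precursor_mz = 2500),
               "precursor")
})
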