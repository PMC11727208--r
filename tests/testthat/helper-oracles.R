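# Independent oracles, kept deliberately separate from the package's own
# arithmetic: residue masses are rebuilt here from IUPAC monoisotopic atomic
# masses and the enumeration oracle is a plain nested loop.

oracle_atomic <- c(H = 1.00782503, C = 12.0, N = 14.0030740,
                   O = 15.9949146, S = 31.9720707, Na = 22.9897693)

oracle_formula_mass <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  sum(c(C, H, N, O, S) * oracle_atomic[c("C", "H", "N", "O", "S")])
}

# permethylated residue increments from their molecular formulas
oracle_res <- c(
  hex    = oracle_formula_mass(C = 9,  H = 16, O = 5),
  hexnac = oracle_formula_mass(C = 11, H = 19, N = 1, O = 5),
  dhex   = oracle_formula_mass(C = 8,  H = 14, O = 4),
  neuac  = oracle_formula_mass(C = 16, H = 27, N = 1, O = 8),
  closure = oracle_formula_mass(C = 2, H = 6, O = 1),
  sulfo  = oracle_formula_mass(S = 1, O = 3) - oracle_formula_mass(C = 1, H = 2)
)

oracle_neutral_mass <- function(hex, hexnac, dhex = 0, neuac = 0, sulfo = 0) {
  hex * oracle_res[["hex"]] + hexnac * oracle_res[["hexnac"]] +
    dhex * oracle_res[["dhex"]] + neuac * oracle_res[["neuac"]] +
    oracle_res[["closure"]] + sulfo * oracle_res[["sulfo"]]
}

oracle_ion_mz <- function(M, polarity, sulfo) {
  H <- oracle_atomic[["H"]]; Na <- oracle_atomic[["Na"]]
  if (polarity == "positive" && sulfo == 0) M + Na
  else if (polarity == "positive") M - sulfo * H + (sulfo + 1) * Na
  else if (sulfo >= 1) M - sulfo * H + (sulfo - 1) * Na
  else NA_real_
}

# exhaustive nested-loop enumeration under the default bounds
oracle_enumerate <- function(target_mz, polarity, tol) {
  hits <- list()
  for (hex in 3:12) for (hexnac in 2:10) for (dhex in 0:4)
    for (neuac in 0:min(6, hexnac - 2)) {
      sulfos <- if (polarity == "negative") seq_len(max(0, min(3, hex - 2)))
                else 0:min(3, hex - 2)
      for (sulfo in sulfos) {
        mz <- oracle_ion_mz(oracle_neutral_mass(hex, hexnac, dhex, neuac,
                                                sulfo), polarity, sulfo)
        if (!is.na(mz) && abs(mz - target_mz) <= tol)
          hits[[length(hits) + 1L]] <-
            data.frame(hex = hex, hexnac = hexnac, dhex = dhex,
                       neuac = neuac, sulfo = sulfo, mz = mz)
      }
    }
  if (!length(hits))
    return(data.frame(hex = integer(), hexnac = integer(), dhex = integer(),
                      neuac = integer(), sulfo = integer(), mz = numeric()))
  do.call(rbind, hits)
}

# canonical key for set comparison of candidate tables
comp_key <- function(df) {
  sort(sprintf("%d:%d:%d:%d:%d", df$hex, df$hexnac, df$dhex, df$neuac,
               df$sulfo))
}

# the sulfated core-fucosylated biantennary used throughout the MS/MS tests
sulfo_biantennary_topology <- function() {
  parse_topology(paste0("GlcNAc(Fuc)(GlcNAc(Man(Man(GlcNAc(Gal[S3])))",
                        "(Man(GlcNAc(Gal)))))"))
}

# annotation recovery: fraction of ground-truth peaks of the given roles
# whose rank-1 assignment equals the generating composition
recovery_rate <- function(sim, roles = "signal", ...) {
  ann <- annotate_spectrum(sim$spectrum, ...)
  truth <- sim$truth[sim$truth$role %in% roles, , drop = FALSE]
  hit <- 0L
  for (i in seq_len(nrow(truth))) {
    j <- which.min(abs(ann$table$mz - truth$mz[i]))
    if (length(j) && isTRUE(ann$table$assigned[j]) &&
        identical(ann$table$composition[j], truth$composition[i]))
      hit <- hit + 1L
  }
  hit / nrow(truth)
}
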