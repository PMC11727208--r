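# Synthetic-data generators: MALDI-TOF reflector peak lists with known
# ground truth, paired normal/tumor cohorts with class-level abundance
# shifts, and paired RPKM expression tables.  Every generator is
# deterministic given its config (which carries the seed).

#' Default glycan ion library for spectrum simulation
#'
#' The compositions dominating the thyroid N-glycome profiles, with
#' realistic relative abundances: for the neutral/sialylated fraction the
#' oligomannose series (Hex5-9HexNAc2) and the core-fucosylated biantennary
#' series with 0-2 sialic acids, plus minor tri-/tetra-antennary and
#' bisect-candidate species; for the sulfated fraction the mono-antennary
#' (1662/1836/1866/2041), biantennary (2112/2286/2647), tri-antennary
#' (2735/3096) mono-sulfated ions and the di-sulfated biantennary (2374).
#'
#' @param fraction `"neutral_sialylated"` or `"sulfated"`.
#' @return Data frame: `composition`, `base_abundance` (median intensity,
#'   arbitrary units).
#' @export
default_glycan_library <- function(fraction = c("neutral_sialylated",
                                                "sulfated")) {
  fraction <- match.arg(fraction)
  if (fraction == "neutral_sialylated")
    data.frame(
      composition = c("Hex5HexNAc2", "Hex6HexNAc2", "Hex7HexNAc2",
                      "Hex8HexNAc2", "Hex9HexNAc2",
                      "Hex5HexNAc4Fuc1", "Hex5HexNAc4Fuc1NeuAc1",
                      "Hex5HexNAc4Fuc1NeuAc2",
                      "Hex6HexNAc5Fuc1NeuAc1", "Hex7HexNAc6Fuc1NeuAc1",
                      "Hex5HexNAc5Fuc1NeuAc2"),
      base_abundance = c(60, 50, 45, 40, 30, 40, 100, 80, 15, 8, 10),
      stringsAsFactors = FALSE)
  else
    data.frame(
      composition = c("Hex4HexNAc3Sulf1", "Hex4HexNAc3Fuc1Sulf1",
                      "Hex5HexNAc3Sulf1", "Hex5HexNAc3Fuc1Sulf1",
                      "Hex5HexNAc4Sulf1", "Hex5HexNAc4Fuc1Sulf1",
                      "Hex5HexNAc4Fuc1NeuAc1Sulf1", "Hex6HexNAc5Fuc1Sulf1",
                      "Hex6HexNAc5Fuc1NeuAc1Sulf1", "Hex5HexNAc4Fuc1Sulf2"),
      base_abundance = c(15, 20, 15, 25, 40, 100, 50, 30, 20, 15),
      stringsAsFactors = FALSE)
}

#' Configuration for spectrum simulation
#'
#' @param library Composition library (see [default_glycan_library()]).
#' @param fraction Spectrum fraction; fixes the polarity (positive for
#'   neutral/sialylated, negative for sulfated).
#' @param sigma_mz Gaussian m/z error SD in Da (reflector-mode calibration).
#' @param sigma_logI Log-scale SD of signal intensities around
#'   `base_abundance`.
#' @param p_under Probability that a signal peak carries a -14 Da
#'   under-permethylation satellite.
#' @param p_disulfo Probability of a +88 Da di-sulfation companion
#'   (sulfated fraction only).
#' @param satellite_ratio Satellite/parent intensity ratio (fixed, so
#'   satellite links remain testable).
#' @param noise_lambda Poisson mean number of noise peaks (uniform m/z over
#'   the range, S/N below the filtering threshold).
#' @param range Acquisition m/z range.
#' @param seed RNG seed; the generator is a pure function of the config.
#' @return An object of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(library = NULL,
                                fraction = c("neutral_sialylated",
                                             "sulfated"),
                                sigma_mz = 0.05, sigma_logI = 0.5,
                                p_under = 0.3, p_disulfo = 0.2,
                                satellite_ratio = 0.2, noise_lambda = 20,
                                range = c(1000, 6000), seed = 1L) {
  fraction <- match.arg(fraction)
  if (is.null(library)) library <- default_glycan_library(fraction)
  stopifnot(nrow(library) >= 1, sigma_mz > 0 || sigma_mz == 0,
            sigma_logI >= 0,
            p_under >= 0, p_under <= 1, p_disulfo >= 0, p_disulfo <= 1)
  polarity <- if (fraction == "sulfated") "negative" else "positive"
  for (cs in library$composition) {
    comp <- parse_composition(cs)
    if (polarity == "negative" && comp$sulfo < 1)
      stop("library entry ", cs, " has no sulfate but the sulfated ",
           "fraction is profiled in negative mode")
    if (polarity == "positive" && comp$sulfo > 0)
      stop("library entry ", cs, " is sulfated but the neutral fraction ",
           "is sulfate-free")
  }
  structure(list(library = library, fraction = fraction,
                 polarity = polarity, sigma_mz = sigma_mz,
                 sigma_logI = sigma_logI, p_under = p_under,
                 p_disulfo = p_disulfo, satellite_ratio = satellite_ratio,
                 noise_lambda = noise_lambda, range = as.numeric(range),
                 seed = as.integer(seed)),
            class = "spectrum_sim_config")
}

# Build one spectrum from per-entry signal intensities (already drawn).
# Returns list(spectrum, truth); truth rows align with spectrum peaks.
.build_spectrum <- function(config, intensities) {
  lib <- config$library
  comps <- lapply(lib$composition, parse_composition)
  theo <- vapply(comps, ion_mz, numeric(1), polarity = config$polarity)
  off <- satellite_offsets()
  n <- nrow(lib)
  rows <- list()
  add <- function(mz, intensity, snr, role, composition, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mz = mz, intensity = intensity, snr = snr, role = role,
      composition = composition, parent = parent, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    mz <- theo[i] + stats::rnorm(1, 0, config$sigma_mz)
    snr <- stats::runif(1, 3, 50)
    add(mz, intensities[i], snr, "signal", lib$composition[i], NA)
    if (stats::runif(1) < config$p_under)
      add(theo[i] + off[["under_permethylation"]] +
            stats::rnorm(1, 0, config$sigma_mz),
          intensities[i] * config$satellite_ratio,
          stats::runif(1, 2, 10), "satellite_under", NA_character_,
          lib$composition[i])
    if (config$fraction == "sulfated" &&
        stats::runif(1) < config$p_disulfo) {
      comp <- comps[[i]]
      dicomp <- glycan_composition(comp$hex, comp$hexnac, comp$dhex,
                                   comp$neuac, comp$sulfo + 1L)
      add(theo[i] + off[["extra_sulfo_salt"]] +
            stats::rnorm(1, 0, config$sigma_mz),
          intensities[i] * config$satellite_ratio,
          stats::runif(1, 2, 10), "satellite_disulfo", format(dicomp),
          lib$composition[i])
    }
  }
  n_noise <- stats::rpois(1, config$noise_lambda)
  if (n_noise > 0)
    for (k in seq_len(n_noise))
      add(stats::runif(1, config$range[1], config$range[2]),
          stats::rlnorm(1, log(5), 1), stats::runif(1, 0.5, 1.9),
          "noise", NA_character_, NA_character_)
  truth <- do.call(rbind, rows)
  ord <- order(truth$mz)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  spec <- glycan_spectrum(truth[, c("mz", "intensity", "snr")],
                          polarity = config$polarity,
                          fraction = config$fraction, range = config$range)
  list(spectrum = spec, truth = truth)
}

#' Simulate a MALDI-TOF reflector peak list with known ground truth
#'
#' One signal peak per library entry at its theoretical ion m/z plus
#' Gaussian error, with log-normal intensities, optional -14 Da
#' under-permethylation and +88 Da di-sulfation satellites at a fixed
#' intensity ratio, and sub-threshold noise peaks.  Fully reproducible from
#' the config's seed.
#'
#' @param config A [spectrum_sim_config()].
#' @return A list: `spectrum` (a [glycan_spectrum()]) and `truth` (data
#'   frame aligned with the spectrum peaks: `mz`, `intensity`, `snr`,
#'   `role` in signal/satellite_under/satellite_disulfo/noise,
#'   `composition` — the generating composition for signal and di-sulfo
#'   satellite peaks — and `parent` composition for satellites).
#' @export
simulate_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  set.seed(config$seed)
  intensities <- config$library$base_abundance *
    exp(stats::rnorm(nrow(config$library), 0, config$sigma_logI))
  .build_spectrum(config, intensities)
}

#' Configuration for paired-cohort simulation
#'
#' Defaults encode the observed tumor-vs-normal directions: branched
#' (antennarity >= 3) and bisect-candidate glycans up, sialylated glycans
#' down, di-sulfated glycans sharply down, oligomannose unchanged.
#'
#' @param n_pairs Number of patients (paired normal/tumor samples).
#' @param multipliers Named tumor/normal abundance multipliers applied to
#'   library entries by class membership (an entry in several classes gets
#'   the product).
#' @param sigma_patient Log-scale SD of the per-patient, per-entry abundance
#'   effect (shared by both members of a pair).
#' @param sigma_resid Log-scale residual SD per sample.
#' @param neutral_config,sulfated_config [spectrum_sim_config()]s for the
#'   two fractions (defaults built from the default libraries).
#' @param seed RNG seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_pairs = 5,
                              multipliers = c(branched = 1.8,
                                              bisect_candidate = 1.8,
                                              sialylated = 0.6,
                                              di_sulfated = 0.4),
                              sigma_patient = 0.5, sigma_resid = 0.3,
                              neutral_config = NULL, sulfated_config = NULL,
                              seed = 1L) {
  stopifnot(n_pairs >= 0, all(multipliers > 0))
  if (is.null(neutral_config))
    neutral_config <- spectrum_sim_config(fraction = "neutral_sialylated")
  if (is.null(sulfated_config))
    sulfated_config <- spectrum_sim_config(fraction = "sulfated")
  structure(list(n_pairs = as.integer(n_pairs), multipliers = multipliers,
                 sigma_patient = sigma_patient, sigma_resid = sigma_resid,
                 neutral_config = neutral_config,
                 sulfated_config = sulfated_config, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# class-membership multiplier for one composition string
.entry_multiplier <- function(comp_string, multipliers) {
  comp <- parse_composition(comp_string)
  cl <- classify(comp)
  mult <- 1
  in_class <- c(
    oligomannose = cl$category == "oligomannose",
    hybrid = cl$category == "hybrid",
    complex = cl$category == "complex",
    branched = cl$antennarity >= 3,
    bisect_candidate = cl$bisect_candidate,
    sialylated = cl$sialylation_count >= 1,
    core_fucosylated = cl$core_fucosylated,
    sulfated = cl$sulfation_count >= 1,
    di_sulfated = cl$sulfation_count >= 2
  )
  for (nm in names(multipliers))
    if (isTRUE(in_class[[nm]])) mult <- mult * multipliers[[nm]]
  mult
}

# true class fractions from per-entry intensities across both fractions
.true_fractions <- function(lib_all, intensities) {
  ann_like <- do.call(rbind, lapply(seq_len(nrow(lib_all)), function(i) {
    cl <- classify(parse_composition(lib_all$composition[i]))
    data.frame(intensity = intensities[i], category = cl$category,
               antennarity = cl$antennarity,
               bisect_candidate = cl$bisect_candidate,
               core_fucosylated = cl$core_fucosylated,
               sialylation_count = cl$sialylation_count,
               sulfation_count = cl$sulfation_count,
               stringsAsFactors = FALSE)
  }))
  total <- sum(ann_like$intensity)
  frac <- function(sel) sum(ann_like$intensity[sel]) / total
  data.frame(
    oligomannose = frac(ann_like$category == "oligomannose"),
    paucimannose = frac(ann_like$category == "paucimannose"),
    hybrid = frac(ann_like$category == "hybrid"),
    complex = frac(ann_like$category == "complex"),
    branched = frac(ann_like$antennarity >= 3),
    bisect_candidate = frac(ann_like$bisect_candidate),
    sialylated = frac(ann_like$sialylation_count >= 1),
    core_fucosylated = frac(ann_like$core_fucosylated),
    sulfated = frac(ann_like$sulfation_count >= 1),
    di_sulfated = frac(ann_like$sulfation_count >= 2))
}

#' Simulate a paired normal/tumor cohort of spectra
#'
#' Per patient, a shared per-entry abundance effect is drawn (log-normal,
#' `sigma_patient`), the tumor member additionally receives the class-level
#' multipliers, and both members get independent residual noise; each
#' member is then rendered as a neutral-fraction and a sulfated-fraction
#' spectrum with the usual m/z error, satellites and noise peaks.
#'
#' @param config A [cohort_sim_config()].
#' @return A list: `samples` — per patient a list with `normal` and `tumor`,
#'   each holding `neutral` and `sulfated` [simulate_spectrum()]-style
#'   results — and `truth`, a data frame of per-sample true class fractions.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  if (config$n_pairs == 0L)
    return(list(samples = list(),
                truth = data.frame(patient = character(),
                                   group = character())))
  lib_n <- config$neutral_config$library
  lib_s <- config$sulfated_config$library
  lib_all <- rbind(lib_n, lib_s)
  mult <- vapply(lib_all$composition, .entry_multiplier, numeric(1),
                 multipliers = config$multipliers)
  n_n <- nrow(lib_n)
  samples <- list()
  truth <- list()
  for (p in seq_len(config$n_pairs)) {
    base <- log(lib_all$base_abundance) +
      stats::rnorm(nrow(lib_all), 0, config$sigma_patient)
    int_normal <- exp(base + stats::rnorm(nrow(lib_all), 0,
                                          config$sigma_resid))
    int_tumor <- exp(base + log(mult) +
                       stats::rnorm(nrow(lib_all), 0, config$sigma_resid))
    render <- function(ints) list(
      neutral = .build_spectrum(config$neutral_config, ints[seq_len(n_n)]),
      sulfated = .build_spectrum(config$sulfated_config, ints[-seq_len(n_n)]))
    pid <- sprintf("P%02d", p)
    samples[[pid]] <- list(normal = render(int_normal),
                           tumor = render(int_tumor))
    truth[[length(truth) + 1L]] <-
      cbind(data.frame(patient = pid, group = "normal"),
            .true_fractions(lib_all, int_normal))
    truth[[length(truth) + 1L]] <-
      cbind(data.frame(patient = pid, group = "tumor"),
            .true_fractions(lib_all, int_tumor))
  }
  list(samples = samples, truth = do.call(rbind, truth))
}

#' Configuration for paired RPKM expression simulation
#'
#' The default gene panel and tumor log2-fold-change signs follow the
#' glycogene comparisons: bisection (MGAT3) and branching (MGAT4B) up,
#' alpha-2,6 sialylation (ST6GAL1) down, MAN1A1 down, MAN1B1 up, GAL3ST3
#' unchanged, GAL3ST4 and the B4GALT3/5/6 galactosyltransferases up.
#'
#' @param lfc Named vector of tumor log2-fold-changes per gene.
#' @param n_pairs Number of patients (default 20, matching the compared
#'   RNAseq cohort size).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline log2-RPKM
#'   distribution.
#' @param sigma_patient SD of the patient random effect (log2 scale; shared
#'   within a pair, cancels in paired differences).
#' @param sigma_resid Residual SD (log2 scale).
#' @param seed RNG seed.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(lfc = c(MGAT3 = 1, MGAT4B = 1,
                                          ST6GAL1 = -1, MAN1A1 = -1,
                                          MAN1B1 = 1, GAL3ST3 = 0,
                                          GAL3ST4 = 1, B4GALT3 = 1,
                                          B4GALT5 = 1, B4GALT6 = 1),
                                  n_pairs = 20,
                                  baseline_log2_mean = 5,
                                  baseline_log2_sd = 1,
                                  sigma_patient = 0.5, sigma_resid = 0.5,
                                  seed = 1L) {
  stopifnot(n_pairs >= 2, sigma_patient > 0, sigma_resid > 0,
            !is.null(names(lfc)))
  structure(list(lfc = lfc, n_pairs = as.integer(n_pairs),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 sigma_patient = sigma_patient, sigma_resid = sigma_resid,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a paired RPKM expression table
#'
#' RPKM = 2^(gene baseline + patient effect + tumor log2-fold-change +
#' residual); the patient effect is shared within a pair so the paired
#' design gains power over an unpaired comparison.
#'
#' @param config An [expression_sim_config()].
#' @return A list: `matrix` (an [expression_matrix()]) and `truth` (data
#'   frame `gene`, `lfc`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  genes <- names(config$lfc)
  n <- config$n_pairs
  mu <- stats::rnorm(length(genes), config$baseline_log2_mean,
                     config$baseline_log2_sd)
  normal_ids <- sprintf("P%02d_N", seq_len(n))
  tumor_ids <- sprintf("P%02d_T", seq_len(n))
  rpkm <- matrix(0, nrow = length(genes), ncol = 2 * n,
                 dimnames = list(genes, c(normal_ids, tumor_ids)))
  for (g in seq_along(genes)) {
    patient <- stats::rnorm(n, 0, config$sigma_patient)
    ln <- mu[g] + patient + stats::rnorm(n, 0, config$sigma_resid)
    lt <- mu[g] + patient + config$lfc[[g]] +
      stats::rnorm(n, 0, config$sigma_resid)
    rpkm[g, normal_ids] <- 2^ln
    rpkm[g, tumor_ids] <- 2^lt
  }
  pairing <- data.frame(patient = sprintf("P%02d", seq_len(n)),
                        normal = normal_ids, tumor = tumor_ids,
                        stringsAsFactors = FALSE)
  list(matrix = expression_matrix(rpkm, pairing),
       truth = data.frame(gene = genes, lfc = unname(config$lfc),
                          stringsAsFactors = FALSE))
}
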