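# Peak-list ingestion, S/N filtering, constrained composition enumeration,
# peak <-> composition assignment, and satellite flagging.

#' Construct a spectrum
#'
#' @param peaks A data frame with numeric columns `mz`, `intensity`, `snr`.
#' @param polarity `"positive"` or `"negative"`.
#' @param fraction `"neutral_sialylated"` (positive-mode pool) or
#'   `"sulfated"` (negative-mode MAX-retained pool).
#' @param range Acquisition m/z range; peaks outside it are dropped by
#'   [filter_peaks()].  Default 1000–6000.
#' @return An object of class `glycan_spectrum`; peaks sorted by m/z.
#' @export
glycan_spectrum <- function(peaks,
                            polarity = c("positive", "negative"),
                            fraction = c("neutral_sialylated", "sulfated"),
                            range = c(1000, 6000)) {
  polarity <- match.arg(polarity)
  fraction <- match.arg(fraction)
  stopifnot(is.data.frame(peaks),
            all(c("mz", "intensity", "snr") %in% names(peaks)))
  peaks <- peaks[, c("mz", "intensity", "snr")]
  if (nrow(peaks) && any(peaks$mz <= 0))
    stop("peak m/z values must be positive")
  if (nrow(peaks) && any(peaks$intensity < 0 | peaks$snr < 0))
    stop("peak intensity and snr must be non-negative")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, polarity = polarity, fraction = fraction,
                 range = as.numeric(range)),
            class = "glycan_spectrum")
}

#' @export
print.glycan_spectrum <- function(x, ...) {
  cat("<glycan_spectrum> ", nrow(x$peaks), " peaks, ", x$polarity,
      " mode, ", x$fraction, " fraction, m/z ", x$range[1], "-",
      x$range[2], "\n", sep = "")
  invisible(x)
}

#' Read a peak list from delimited text
#'
#' Expects a header with columns `mz`, `intensity` and optionally `snr`
#' (comma- or tab-delimited, auto-detected).  When `snr` is absent it is
#' imputed as `intensity / median(intensity)` with a warning, mirroring the
#' common situation where exported centroid lists carry intensities only.
#'
#' @param path Path to the peak-list file.
#' @inheritParams glycan_spectrum
#' @return A [glycan_spectrum()], peaks sorted by m/z.
#' @export
read_peaklist <- function(path, polarity = c("positive", "negative"),
                          fraction = c("neutral_sialylated", "sulfated"),
                          range = c(1000, 6000)) {
  polarity <- match.arg(polarity)
  fraction <- match.arg(fraction)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("empty peak list: ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  need <- c("mz", "intensity")
  if (!all(need %in% header))
    stop("peak list must have header columns 'mz' and 'intensity': ", path)
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  parse_col <- function(col) {
    vals <- vapply(rows, function(r) if (length(r) >= col) trimws(r[col])
                                     else NA_character_, character(1))
    suppressWarnings(as.numeric(vals))
  }
  mz <- parse_col(match("mz", header))
  intensity <- parse_col(match("intensity", header))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad))
    stop("unparseable peak-list row at line ", bad[1] + 1L, " of ", path)
  if ("snr" %in% header) {
    snr <- parse_col(match("snr", header))
    bad <- which(is.na(snr))
    if (length(bad))
      stop("unparseable peak-list row at line ", bad[1] + 1L, " of ", path)
  } else {
    warning("no 'snr' column in ", path,
            "; imputing snr = intensity / median(intensity)")
    snr <- intensity / stats::median(intensity)
  }
  glycan_spectrum(data.frame(mz = mz, intensity = intensity, snr = snr),
                  polarity = polarity, fraction = fraction, range = range)
}

#' Filter peaks by signal-to-noise and acquisition range
#'
#' Retains peaks with `snr >= min_snr` (the profiling default is a
#' signal/noise ratio of at least 2) and m/z inside the spectrum range.
#'
#' @param spectrum A [glycan_spectrum()].
#' @param min_snr Minimum signal-to-noise ratio (inclusive).
#' @return The filtered [glycan_spectrum()]; may be empty.
#' @export
filter_peaks <- function(spectrum, min_snr = 2.0) {
  stopifnot(inherits(spectrum, "glycan_spectrum"))
  keep <- spectrum$peaks$snr >= min_snr &
    spectrum$peaks$mz >= spectrum$range[1] &
    spectrum$peaks$mz <= spectrum$range[2]
  spectrum$peaks <- spectrum$peaks[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Bounds and plausibility rules for composition enumeration
#'
#' Defines the residue-count search space for [enumerate_compositions()].
#' With `n_glycan_core = TRUE` the minima are the trimannosyl-chitobiose
#' core (Hex >= 3, HexNAc >= 2).  The plausibility rules cap terminal
#' substituents by available attachment points: `NeuAc <= HexNAc - 2`
#' (each sialic acid caps an antennal galactose) and `Sulf <= Hex - 2`.
#'
#' @param hex_max,hexnac_max,dhex_max,neuac_max,sulfo_max Maximum counts.
#' @param n_glycan_core Enforce core minima?
#' @param plausibility Apply the substituent capacity rules?
#' @return An object of class `composition_bounds`.
#' @export
composition_bounds <- function(hex_max = 12, hexnac_max = 10, dhex_max = 4,
                               neuac_max = 6, sulfo_max = 3,
                               n_glycan_core = TRUE, plausibility = TRUE) {
  hex_min <- if (n_glycan_core) 3L else 0L
  hexnac_min <- if (n_glycan_core) 2L else 0L
  if (hex_max < hex_min || hexnac_max < hexnac_min)
    stop("bounds must admit the N-glycan core minima")
  structure(list(hex = c(hex_min, as.integer(hex_max)),
                 hexnac = c(hexnac_min, as.integer(hexnac_max)),
                 dhex = c(0L, as.integer(dhex_max)),
                 neuac = c(0L, as.integer(neuac_max)),
                 sulfo = c(0L, as.integer(sulfo_max)),
                 n_glycan_core = n_glycan_core,
                 plausibility = plausibility),
            class = "composition_bounds")
}

# Full candidate grid under bounds, with ion m/z for the given polarity.
# In negative mode only sulfated compositions ionize; in positive mode all do.
.composition_grid <- function(polarity, bounds) {
  sulfo_min <- if (polarity == "negative") max(1L, bounds$sulfo[1])
               else bounds$sulfo[1]
  if (sulfo_min > bounds$sulfo[2])
    return(data.frame(hex = integer(), hexnac = integer(), dhex = integer(),
                      neuac = integer(), sulfo = integer(), mz = numeric()))
  g <- expand.grid(hex = bounds$hex[1]:bounds$hex[2],
                   hexnac = bounds$hexnac[1]:bounds$hexnac[2],
                   dhex = bounds$dhex[1]:bounds$dhex[2],
                   neuac = bounds$neuac[1]:bounds$neuac[2],
                   sulfo = sulfo_min:bounds$sulfo[2],
                   KEEP.OUT.ATTRS = FALSE)
  if (bounds$plausibility)
    g <- g[g$neuac <= g$hexnac - 2L & g$sulfo <= g$hex - 2L, , drop = FALSE]
  mc <- .mass_const
  M <- g$hex * mc$hex + g$hexnac * mc$hexnac + g$dhex * mc$dhex +
    g$neuac * mc$neuac + mc$closure + g$sulfo * mc$sulfo
  g$mz <- if (polarity == "positive")
    ifelse(g$sulfo == 0, M + mc$Na,
           M - g$sulfo * mc$H + (g$sulfo + 1) * mc$Na)
  else
    M - g$sulfo * mc$H + (g$sulfo - 1) * mc$Na
  rownames(g) <- NULL
  g
}

.comp_string <- function(g) {
  out <- character(nrow(g))
  toks <- c("Hex", "HexNAc", "Fuc", "NeuAc", "Sulf")
  cols <- c("hex", "hexnac", "dhex", "neuac", "sulfo")
  for (i in seq_along(toks)) {
    n <- g[[cols[i]]]
    out <- paste0(out, ifelse(n > 0, paste0(toks[i], n), ""))
  }
  out
}

#' Enumerate compositions matching a target m/z
#'
#' Returns exactly the compositions within `bounds` whose singly charged ion
#' m/z (under the polarity's adduct conventions) lies within
#' `tolerance_da` of `target_mz`, sorted by absolute mass error.  Ties are
#' broken by parsimony: fewer total residues first, then fewer sulfates,
#' then the lexicographic canonical string — a policy, since curated
#' annotation resolves such ties manually.
#'
#' @param target_mz Target m/z (Th).
#' @param polarity `"positive"` or `"negative"`.
#' @param tolerance_da Matching tolerance in Da (> 0).
#' @param bounds A [composition_bounds()].
#' @return A data frame with columns `composition`, `hex`, `hexnac`, `dhex`,
#'   `neuac`, `sulfo`, `mz`, `error` (computed - target, Da), ordered
#'   deterministically; zero rows when nothing matches.
#' @export
enumerate_compositions <- function(target_mz,
                                   polarity = c("positive", "negative"),
                                   tolerance_da = 0.5,
                                   bounds = composition_bounds()) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(bounds, "composition_bounds"), tolerance_da > 0)
  g <- .composition_grid(polarity, bounds)
  g$error <- g$mz - target_mz
  g <- g[abs(g$error) <= tolerance_da, , drop = FALSE]
  g$composition <- .comp_string(g)
  tot <- g$hex + g$hexnac + g$dhex + g$neuac
  g <- g[order(abs(g$error), tot, g$sulfo, g$composition), , drop = FALSE]
  rownames(g) <- NULL
  g[, c("composition", "hex", "hexnac", "dhex", "neuac", "sulfo",
        "mz", "error")]
}

#' Annotate a spectrum with glycan compositions
#'
#' Filters peaks ([filter_peaks()]), then assigns each retained peak the
#' compositions whose ion m/z falls within `tolerance_da`
#' ([enumerate_compositions()]).  The neutral/sialylated fraction is matched
#' against positive-mode sulfate-free ions; the sulfated fraction against
#' negative-mode sulfated ions.  Peaks with no candidate are kept and marked
#' unassigned — these correspond to the asterisked signals of a curated
#' profile.
#'
#' @param spectrum A [glycan_spectrum()].
#' @param bounds A [composition_bounds()]; for the neutral fraction the
#'   sulfate bound is forced to 0.
#' @param tolerance_da Matching tolerance in Da.
#' @param min_snr Signal-to-noise threshold applied before annotation.
#' @return An object of class `glycan_annotations`: a list with `table`
#'   (one row per retained peak: m/z, intensity, snr, rank-1 composition and
#'   class fields, mass error, candidate count) and `candidates` (per-peak
#'   data frames from [enumerate_compositions()]), plus the spectrum
#'   metadata.
#' @export
annotate_spectrum <- function(spectrum, bounds = composition_bounds(),
                              tolerance_da = 0.5, min_snr = 2.0) {
  stopifnot(inherits(spectrum, "glycan_spectrum"))
  ok <- (spectrum$fraction == "neutral_sialylated" &&
           spectrum$polarity == "positive") ||
        (spectrum$fraction == "sulfated" && spectrum$polarity == "negative")
  if (!ok)
    stop("polarity/fraction mismatch: ", spectrum$fraction,
         " fraction requires ",
         if (spectrum$fraction == "sulfated") "negative" else "positive",
         " mode")
  if (spectrum$fraction == "neutral_sialylated")
    bounds$sulfo <- c(0L, 0L)
  spectrum <- filter_peaks(spectrum, min_snr = min_snr)
  pk <- spectrum$peaks
  n <- nrow(pk)
  cands <- vector("list", n)
  tab <- data.frame(
    peak_id = seq_len(n), mz = pk$mz, intensity = pk$intensity,
    snr = pk$snr, assigned = logical(n),
    composition = NA_character_, ion_mz = NA_real_, error_da = NA_real_,
    n_candidates = 0L, category = NA_character_, antennarity = NA_integer_,
    bisect_candidate = NA, core_fucosylated = NA,
    sialylation_count = NA_integer_, sulfation_count = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cc <- enumerate_compositions(pk$mz[i], spectrum$polarity,
                                 tolerance_da, bounds)
    cands[[i]] <- cc
    tab$n_candidates[i] <- nrow(cc)
    if (nrow(cc)) {
      tab$assigned[i] <- TRUE
      tab$composition[i] <- cc$composition[1]
      tab$ion_mz[i] <- cc$mz[1]
      tab$error_da[i] <- cc$error[1]
      comp <- glycan_composition(cc$hex[1], cc$hexnac[1], cc$dhex[1],
                                 cc$neuac[1], cc$sulfo[1])
      if (is_n_glycan(comp)) {
        cl <- classify(comp)
        tab$category[i] <- cl$category
        tab$antennarity[i] <- cl$antennarity
        tab$bisect_candidate[i] <- cl$bisect_candidate
        tab$core_fucosylated[i] <- cl$core_fucosylated
        tab$sialylation_count[i] <- cl$sialylation_count
        tab$sulfation_count[i] <- cl$sulfation_count
      }
    }
  }
  structure(list(table = tab, candidates = cands,
                 polarity = spectrum$polarity, fraction = spectrum$fraction,
                 range = spectrum$range, tolerance_da = tolerance_da,
                 satellites = NULL),
            class = "glycan_annotations")
}

#' @export
print.glycan_annotations <- function(x, ...) {
  cat("<glycan_annotations> ", nrow(x$table), " peaks (",
      sum(x$table$assigned), " assigned), ", x$polarity, " mode, ",
      x$fraction, " fraction, tol ", x$tolerance_da, " Da\n", sep = "")
  invisible(x)
}

#' Flag under-permethylation and di-sulfation satellite peaks
#'
#' Links peak pairs whose spacing matches the known satellite offsets:
#' a peak 14.0157 Da below another is flagged as its under-permethylation
#' satellite (one missing methyl), and — in the sulfated fraction — a peak
#' 87.9231 Da above another is flagged as a di-sulfation candidate of it
#' (the +88 Da sodium-salt spacing).  Links annotate the table only; rank-1
#' assignments are never altered.
#'
#' @param annotations A `glycan_annotations` object.
#' @param tolerance_da Pair-spacing tolerance in Da.
#' @return The annotations with a `satellites` data frame (`label`,
#'   `peak_id`, `parent_id`, `delta`) and logical table columns
#'   `under_permethylation_satellite`, `disulfo_candidate`.
#' @export
flag_satellites <- function(annotations, tolerance_da = 0.3) {
  stopifnot(inherits(annotations, "glycan_annotations"))
  tab <- annotations$table
  off <- satellite_offsets()
  links <- list()
  if (nrow(tab) >= 2) {
    mz <- tab$mz
    for (i in seq_along(mz)) {
      d <- mz - mz[i]
      up <- which(abs(d - (-off[["under_permethylation"]])) <= tolerance_da)
      for (j in up)
        links[[length(links) + 1L]] <- data.frame(
          label = "under_permethylation", peak_id = tab$peak_id[i],
          parent_id = tab$peak_id[j], delta = mz[i] - mz[j])
      if (annotations$fraction == "sulfated") {
        ds <- which(abs(d - (-off[["extra_sulfo_salt"]])) <= tolerance_da)
        for (j in ds)
          links[[length(links) + 1L]] <- data.frame(
            label = "di_sulfation_candidate", peak_id = tab$peak_id[i],
            parent_id = tab$peak_id[j], delta = mz[i] - mz[j])
      }
    }
  }
  sat <- if (length(links)) do.call(rbind, links)
         else data.frame(label = character(), peak_id = integer(),
                         parent_id = integer(), delta = numeric())
  tab$under_permethylation_satellite <-
    tab$peak_id %in% sat$peak_id[sat$label == "under_permethylation"]
  tab$disulfo_candidate <-
    tab$peak_id %in% sat$peak_id[sat$label == "di_sulfation_candidate"]
  annotations$table <- tab
  annotations$satellites <- sat
  annotations
}

#' Write an annotation report as TSV
#'
#' One row per retained peak: m/z, intensity, rank-1 composition, ion
#' species, mass error (mDa), class fields, satellite flags and a compact
#' JSON column holding all candidates.  Output is deterministic: a fixed
#' column order and fixed numeric formatting, so identical inputs yield
#' byte-identical files.
#'
#' @param annotations A `glycan_annotations` object (satellite columns are
#'   added via [flag_satellites()] if missing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "glycan_annotations"))
  if (is.null(annotations$satellites))
    annotations <- flag_satellites(annotations)
  tab <- annotations$table
  cand_json <- vapply(annotations$candidates, function(cc) {
    if (!nrow(cc)) return("[]")
    paste0("[", paste0(sprintf(
      '{"composition":"%s","mz":%.4f,"error":%.4f}',
      cc$composition, cc$mz, cc$error), collapse = ","), "]")
  }, character(1))
  out <- data.frame(
    mz = sprintf("%.4f", tab$mz),
    intensity = sprintf("%.4f", tab$intensity),
    snr = sprintf("%.2f", tab$snr),
    composition = ifelse(tab$assigned, tab$composition, "unassigned"),
    ion = paste0(annotations$polarity,
                 ifelse(is.na(tab$sulfation_count), "",
                        paste0("/sulfo", tab$sulfation_count))),
    error_mda = ifelse(tab$assigned, sprintf("%.1f", tab$error_da * 1000), ""),
    category = ifelse(is.na(tab$category), "", tab$category),
    antennarity = ifelse(is.na(tab$antennarity), "", tab$antennarity),
    bisect_candidate = ifelse(is.na(tab$bisect_candidate), "",
                              tab$bisect_candidate),
    core_fucosylated = ifelse(is.na(tab$core_fucosylated), "",
                              tab$core_fucosylated),
    under_permethylation_satellite = tab$under_permethylation_satellite,
    disulfo_candidate = tab$disulfo_candidate,
    candidates_json = cand_json,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
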