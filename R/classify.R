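# Composition-level N-glycan classification and in-silico exoglycosidase
# transforms.  Classification is heuristic by construction: a composition
# does not determine a topology, so bisection and core-vs-antennary fucose
# are reported as candidates/flags, never as certainties.

#' Classify an N-glycan composition
#'
#' Assigns a structural category and feature flags from residue counts alone:
#' \describe{
#'   \item{category}{`oligomannose` if HexNAc == 2 and Hex >= 5;
#'     `paucimannose` if HexNAc == 2 and Hex <= 4; `hybrid` if HexNAc == 3
#'     and Hex >= 5; otherwise `complex`.}
#'   \item{antennarity}{`min(HexNAc - 2, 4)` for hybrid/complex glycans and
#'     0 for (pauci)oligomannose — each antenna beyond the core adds one
#'     HexNAc, capped at 4.}
#'   \item{bisect_candidate}{`TRUE` when the HexNAc surplus over the
#'     chitobiose exceeds the Hex surplus over the trimannosyl core
#'     (`HexNAc - 2 > Hex - 3`): an extra HexNAc without its galactose is
#'     consistent with — but does not prove — a bisecting GlcNAc.}
#'   \item{core_fucosylated}{`TRUE` when any deoxyhexose is present; in
#'     thyroid N-glycomes fucosylation is overwhelmingly on the core, so the
#'     composition-level call maps dHex >= 1 to core fucosylation.
#'     Topology-level fragment evidence can override.}
#' }
#'
#' @param comp A [glycan_composition()] satisfying [is_n_glycan()].
#' @return An object of class `glycan_class`: a list with `category`,
#'   `antennarity`, `bisect_candidate`, `core_fucosylated`,
#'   `sialylation_count`, `sulfation_count`.
#' @examples
#' classify(parse_composition("Hex5HexNAc4Fuc1NeuAc1"))
#' @export
classify <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (!is_n_glycan(comp))
    stop("not an N-glycan composition (requires HexNAc >= 2 and Hex >= 3): ",
         format(comp))
  category <-
    if (comp$hexnac == 2L && comp$hex >= 5L) "oligomannose"
    else if (comp$hexnac == 2L) "paucimannose"
    else if (comp$hexnac == 3L && comp$hex >= 5L) "hybrid"
    else "complex"
  antennarity <- if (category %in% c("oligomannose", "paucimannose")) 0L
                 else min(comp$hexnac - 2L, 4L)
  structure(list(
    category = category,
    antennarity = antennarity,
    bisect_candidate = (comp$hexnac - 2L) > (comp$hex - 3L),
    core_fucosylated = comp$dhex >= 1L,
    sialylation_count = comp$neuac,
    sulfation_count = comp$sulfo
  ), class = "glycan_class")
}

#' @export
print.glycan_class <- function(x, ...) {
  cat("<glycan_class> ", x$category,
      ", antennarity ", x$antennarity,
      if (x$bisect_candidate) ", bisect candidate",
      if (x$core_fucosylated) ", core-fucosylated",
      ", NeuAc ", x$sialylation_count,
      ", sulfo ", x$sulfation_count, "\n", sep = "")
  invisible(x)
}

#' In-silico desialylation
#'
#' Models exoglycosidase treatment of a composition.  Sialidase A (broad
#' specificity) removes all NeuAc.  Sialidase S hydrolyzes only
#' alpha-2,3-linked sialic acids, so it removes `round(neuac *
#' alpha23_fraction)` residues; the default fraction is 0 because thyroid
#' N-glycan sialylation is dominated by the alpha-2,6 linkage, leaving
#' sialidase S without substrate.
#'
#' @param comp A [glycan_composition()].
#' @param enzyme `"sialidaseA"` or `"sialidaseS"`.
#' @param alpha23_fraction Fraction of NeuAc residues that are
#'   alpha-2,3-linked, in \[0, 1\].  Used by sialidase S only.
#' @return The treated [glycan_composition()].
#' @examples
#' desialylate(parse_composition("Hex5HexNAc4Fuc1NeuAc2"), "sialidaseA")
#' @export
desialylate <- function(comp, enzyme = c("sialidaseA", "sialidaseS"),
                        alpha23_fraction = 0) {
  stopifnot(inherits(comp, "glycan_composition"))
  enzyme <- match.arg(enzyme)
  if (!is.numeric(alpha23_fraction) || length(alpha23_fraction) != 1L ||
      is.na(alpha23_fraction) || alpha23_fraction < 0 || alpha23_fraction > 1)
    stop("alpha23_fraction must be a single value in [0, 1]")
  removed <- switch(enzyme,
    sialidaseA = comp$neuac,
    sialidaseS = as.integer(round(comp$neuac * alpha23_fraction))
  )
  glycan_composition(hex = comp$hex, hexnac = comp$hexnac, dhex = comp$dhex,
                     neuac = comp$neuac - removed, sulfo = comp$sulfo)
}
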