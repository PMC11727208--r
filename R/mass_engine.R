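# Mass calculus for fully permethylated, optionally sulfated N-glycans and
# their singly charged MALDI ions.
#
# Neutral masses are quoted for the free-acid form (all sulfates protonated).
# Ion conventions, all singly charged:
#   positive, no sulfate : [M + Na]+                      (sodiated)
#   negative, n sulfates : [M - nH + (n-1)Na]-            (all sulfates
#                          deprotonated, n-1 sodium counterions)
#   positive, n sulfates : [M - nH + (n+1)Na]+            (sodium-salt form)
# Sulfated glycans are only detected in negative mode in the profiling
# workflow; requesting a negative ion for a sulfate-free composition is an
# error.

#' Ion species for singly charged MALDI glycan ions
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param n_sulfo Number of sulfate groups carried by the composition the
#'   species will be applied to.  Negative species require `n_sulfo >= 1`.
#' @return An object of class `ion_species` with fields `polarity`,
#'   `n_sulfo`, `charge` (always 1) and `adduct_shift` (Da, added to the
#'   free-acid neutral mass to obtain m/z).
#' @examples
#' ion_species("negative", n_sulfo = 1)
#' @export
ion_species <- function(polarity = c("positive", "negative"), n_sulfo = 0) {
  polarity <- match.arg(polarity)
  n_sulfo <- as.integer(n_sulfo)
  if (is.na(n_sulfo) || n_sulfo < 0)
    stop("n_sulfo must be a non-negative integer")
  if (polarity == "negative" && n_sulfo < 1)
    stop("negative-mode ions require at least one sulfate ",
         "(the sulfated pool is profiled in negative mode only)")
  H <- .mass_const$H; Na <- .mass_const$Na
  shift <- if (polarity == "positive" && n_sulfo == 0) Na
           else if (polarity == "negative") -n_sulfo * H + (n_sulfo - 1) * Na
           else -n_sulfo * H + (n_sulfo + 1) * Na
  structure(list(polarity = polarity, n_sulfo = n_sulfo, charge = 1L,
                 adduct_shift = shift),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion_species> ", x$polarity, ", ", x$n_sulfo, " sulfo, shift ",
      sprintf("%+.4f", x$adduct_shift), " Da\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a permethylated glycan (free-acid form)
#'
#' Sum of permethylated residue masses plus the free-reducing-end closure,
#' plus one `SO3 - CH2` delta per sulfate (the sulfated site escapes
#' methylation).
#'
#' @param comp A [glycan_composition()].
#' @return Mass in Da.
#' @examples
#' neutral_mass(parse_composition("Hex5HexNAc2"))  # 1556.793
#' @export
neutral_mass <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  with(.mass_const,
       comp$hex * hex + comp$hexnac * hexnac + comp$dhex * dhex +
       comp$neuac * neuac + closure + comp$sulfo * sulfo)
}

#' m/z of the singly charged MALDI ion of a permethylated glycan
#'
#' Applies the ion conventions described in the package overview.  When
#' `species` is omitted it is derived from `polarity` and the composition's
#' sulfate count.
#'
#' @param comp A [glycan_composition()].
#' @param polarity `"positive"` or `"negative"`; ignored when `species`
#'   is supplied.
#' @param species Optional [ion_species()]; must be consistent with
#'   `comp$sulfo`.
#' @return m/z in Th (singly charged, so numerically Da).
#' @examples
#' ion_mz(parse_composition("Hex5HexNAc2"), "positive")             # 1579.78
#' ion_mz(parse_composition("Hex5HexNAc4Fuc1Sulf1"), "negative")    # 2286.07
#' @export
ion_mz <- function(comp, polarity = c("positive", "negative"),
                   species = NULL) {
  stopifnot(inherits(comp, "glycan_composition"))
  if (is.null(species)) {
    polarity <- match.arg(polarity)
    species <- ion_species(polarity, n_sulfo = comp$sulfo)
  }
  stopifnot(inherits(species, "ion_species"))
  if (species$n_sulfo != comp$sulfo)
    stop("ion species declares ", species$n_sulfo, " sulfates but the ",
         "composition carries ", comp$sulfo)
  neutral_mass(comp) + species$adduct_shift
}
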