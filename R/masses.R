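# Monoisotopic mass tables for fully permethylated glycans.
#
# Residue masses are the permethylated residue increments (the mass a residue
# adds when condensed into a permethylated chain).  The closure term accounts
# for the two chain termini of a free-reducing-end permethylated glycan
# (reducing-end O-methyl + non-reducing-end methyl, net C2H6O).  A sulfated
# site escapes methylation, so each sulfate contributes SO3 - CH2 relative to
# the fully methylated glycan.

.atomic <- c(
  H  = 1.00783,
  C  = 12.0,
  O  = 15.99491,
  S  = 31.97207,
  Na = 22.98977
)

.mass_const <- list(
  hex       = 204.0998,  # C9H16O5, permethylated hexose residue
  hexnac    = 245.1263,  # C11H19NO5, permethylated HexNAc residue
  dhex      = 174.0892,  # C8H14O4, permethylated deoxyhexose (Fuc) residue
  neuac     = 361.1737,  # C17H27NO8, permethylated NeuAc residue
  closure   = 46.0419,   # C2H6O, chain termini of a free-reducing-end glycan
  H         = 1.00783,
  Na        = 22.98977,
  CH2       = 14.01565,
  SO3       = 79.95682,
  H2O       = 18.01056,
  # sulfated site is unmethylated: +SO3 - CH2
  sulfo     = 79.95682 - 14.01565,
  # non-reducing B-type terminus of a permethylated oxocarbenium (CH3 + 2H
  # bookkeeping under the frozen fragment conventions)
  b_terminus = 15.0229,
  # sodiation: Na replaces H
  sodiation  = 22.98977 - 1.00783
)

#' Monoisotopic residue-mass table for permethylated glycans
#'
#' Returns the residue increment masses used throughout the package, in
#' daltons (monoisotopic).  `hex`, `hexnac`, `dhex` and `neuac` are the
#' permethylated residue masses; `closure` is the end-group mass of a
#' free-reducing-end permethylated glycan; `sulfo` is the per-sulfate delta
#' (+SO3 \eqn{-} CH2, because the sulfated hydroxyl escapes methylation).
#'
#' @return A named numeric vector of masses in Da.
#' @examples
#' residue_masses()[["hex"]]
#' @export
residue_masses <- function() {
  unlist(.mass_const[c("hex", "hexnac", "dhex", "neuac", "closure",
                       "sulfo", "H", "Na", "CH2", "SO3")])
}

#' Satellite-peak mass offsets
#'
#' Offsets (Da) linking a fully permethylated parent ion to its common
#' companion signals: `under_permethylation` is the -14 Da satellite from one
#' missing methyl group; `extra_sulfo_salt` is the +88 Da spacing between the
#' singly charged ions of the mono- and di-sulfated forms of the same glycan
#' under the sodium-salt conventions (SO3 \eqn{-} CH2 + Na \eqn{-} H).
#'
#' @return Named numeric vector of two offsets in Da.
#' @examples
#' round(satellite_offsets()["extra_sulfo_salt"])  # 88
#' @export
satellite_offsets <- function() {
  c(
    under_permethylation = -.mass_const$CH2,
    extra_sulfo_salt = .mass_const$sulfo + .mass_const$Na - .mass_const$H
  )
}
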