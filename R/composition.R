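# Glycan composition: residue counts plus sulfate count, the unit of
# annotation.  Canonical string grammar:
#   ("Hex" INT)? ("HexNAc" INT)? ("Fuc" INT)? ("NeuAc" INT)? ("Sulf" INT)?
# with at least one clause; canonical clause order Hex, HexNAc, Fuc, NeuAc,
# Sulf; zero-count clauses are omitted on rendering.

.comp_fields <- c("hex", "hexnac", "dhex", "neuac", "sulfo")
.comp_tokens <- c(Hex = "hex", HexNAc = "hexnac", Fuc = "dhex",
                  NeuAc = "neuac", Sulf = "sulfo")

#' Construct a glycan composition
#'
#' A `glycan_composition` is a set of residue counts — hexose (`hex`),
#' N-acetylhexosamine (`hexnac`), deoxyhexose/fucose (`dhex`),
#' N-acetylneuraminic acid (`neuac`) — plus a sulfate count (`sulfo`).
#' All counts are non-negative integers and at least one residue count
#' must be positive.
#'
#' @param hex,hexnac,dhex,neuac,sulfo Non-negative integer counts.
#' @return An object of class `glycan_composition`.
#' @examples
#' glycan_composition(hex = 5, hexnac = 2)
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0,
                               sulfo = 0) {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac,
              sulfo = sulfo)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  if (sum(counts[c("hex", "hexnac", "dhex", "neuac")]) == 0L)
    stop("composition must contain at least one residue")
  structure(as.list(as.integer(counts)), names = .comp_fields,
            class = "glycan_composition")
}

#' Parse a composition string
#'
#' Parses the canonical composition grammar, e.g. `"Hex5HexNAc4Fuc1NeuAc1"`.
#' Clauses may appear in any order but each at most once; unknown tokens and
#' malformed counts are errors that name the offending text.
#'
#' @param text A single composition string.
#' @return A [glycan_composition()].
#' @examples
#' parse_composition("Hex5HexNAc4Fuc1NeuAc1")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("composition string must be a single non-empty character value")
  m <- gregexpr("([A-Za-z]+)([0-9]+)", text, perl = TRUE)[[1]]
  clauses <- regmatches(text, gregexpr("([A-Za-z]+)([0-9]+)", text))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(text))
    stop("malformed composition string: ", sQuote(text))
  counts <- stats::setNames(integer(5), .comp_fields)
  seen <- character(0)
  for (cl in clauses) {
    tok <- sub("[0-9]+$", "", cl)
    n <- as.integer(sub("^[A-Za-z]+", "", cl))
    if (!tok %in% names(.comp_tokens))
      stop("unknown residue token ", sQuote(tok), " in ", sQuote(text))
    if (tok %in% seen)
      stop("duplicated clause ", sQuote(tok), " in ", sQuote(text))
    if (n == 0L)
      stop("zero count for ", sQuote(tok), " in ", sQuote(text),
           "; omit the clause instead")
    seen <- c(seen, tok)
    counts[.comp_tokens[[tok]]] <- n
  }
  do.call(glycan_composition, as.list(counts))
}

#' Render a composition in canonical form
#'
#' @param x A `glycan_composition`.
#' @param ... Unused.
#' @return The canonical composition string (clause order Hex, HexNAc, Fuc,
#'   NeuAc, Sulf; zero counts omitted).
#' @export
format.glycan_composition <- function(x, ...) {
  toks <- names(.comp_tokens)
  counts <- unlist(x)[.comp_tokens]
  paste0(toks[counts > 0], counts[counts > 0], collapse = "")
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x, ...)

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan_composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.glycan_composition` <- function(e1, e2) {
  identical(unlist(e1), unlist(e2))
}

#' Does a composition satisfy the N-glycan core?
#'
#' N-glycans carry a trimannosyl-chitobiose core, so a plausible N-glycan
#' composition needs at least two HexNAc (the chitobiose) and three Hex
#' (the core mannoses).
#'
#' @param comp A [glycan_composition()].
#' @return Logical scalar.
#' @export
is_n_glycan <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  comp$hexnac >= 2L && comp$hex >= 3L
}

#' Total monosaccharide residue count (sulfates excluded)
#' @param comp A [glycan_composition()].
#' @return Integer.
#' @export
residue_count <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  comp$hex + comp$hexnac + comp$dhex + comp$neuac
}
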