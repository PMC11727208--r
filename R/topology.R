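# Rooted glycan topologies.  Text grammar (nested parentheses, root first,
# reducing end at the root):
#
#   node     := RESIDUE sulfo? child*
#   child    := "(" node ")"
#   sulfo    := "[S" POSITION "]"        e.g. Gal[S3] = 3-O-sulfated Gal
#   RESIDUE  := Man | Gal | Glc | GlcNAc | GalNAc | Fuc | NeuAc
#
# Example (sulfated biantennary, core-fucosylated):
#   GlcNAc(Fuc)(GlcNAc(Man(Man(GlcNAc(Gal[S3])))(Man(GlcNAc(Gal)))))

.residue_class <- c(Man = "hex", Gal = "hex", Glc = "hex",
                    GlcNAc = "hexnac", GalNAc = "hexnac",
                    Fuc = "dhex", NeuAc = "neuac")

#' Parse a glycan topology string
#'
#' Parses the nested-parenthesis tree grammar (see the package vignette for
#' the full grammar).  The first residue is the root and carries the
#' reducing end; `[S<pos>]` after a residue marks an O-sulfated site, e.g.
#' `Gal[S3]` for 3-O-sulfated galactose.
#'
#' @param text A topology string.
#' @return An object of class `glycan_topology`: a list with `nodes` (data
#'   frame: `id`, `residue`, `class`, `sulfo_pos`, `parent`) and the source
#'   `text`.  Node 1 is the root; every other node's `parent` is the node it
#'   is glycosidically linked to.
#' @examples
#' parse_topology("GlcNAc(Fuc)(GlcNAc(Man(Man(GlcNAc(Gal[S3])))(Man(GlcNAc(Gal)))))")
#' @export
parse_topology <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  src <- gsub("[[:space:]]", "", text)
  pos <- 1L
  n <- nchar(src)
  nodes <- list()
  peek <- function() if (pos <= n) substr(src, pos, pos) else ""
  parse_node <- function(parent) {
    m <- regmatches(substr(src, pos, n),
                    regexpr("^[A-Za-z]+", substr(src, pos, n)))
    if (!length(m))
      stop("expected a residue name at position ", pos, " of ", sQuote(text))
    res <- m
    if (!res %in% names(.residue_class))
      stop("unknown residue ", sQuote(res), " in topology ", sQuote(text))
    pos <<- pos + nchar(res)
    sulfo_pos <- NA_character_
    if (peek() == "[") {
      sm <- regmatches(substr(src, pos, n),
                       regexpr("^\\[S[0-9]+\\]", substr(src, pos, n)))
      if (!length(sm))
        stop("malformed sulfo site at position ", pos, " of ", sQuote(text))
      sulfo_pos <- sub("\\]$", "", sub("^\\[S", "", sm))
      pos <<- pos + nchar(sm)
    }
    id <- length(nodes) + 1L
    nodes[[id]] <<- data.frame(id = id, residue = res,
                               class = .residue_class[[res]],
                               sulfo_pos = sulfo_pos, parent = parent,
                               stringsAsFactors = FALSE)
    while (peek() == "(") {
      pos <<- pos + 1L
      parse_node(id)
      if (peek() != ")")
        stop("unbalanced parentheses at position ", pos, " of ", sQuote(text))
      pos <<- pos + 1L
    }
    id
  }
  parse_node(0L)
  if (pos <= n)
    stop("trailing characters at position ", pos, " of ", sQuote(text))
  structure(list(nodes = do.call(rbind, nodes), text = src),
            class = "glycan_topology")
}

#' @export
print.glycan_topology <- function(x, ...) {
  cat("<glycan_topology> ", nrow(x$nodes), " residues, ",
      sum(!is.na(x$nodes$sulfo_pos)), " sulfated site(s): ", x$text, "\n",
      sep = "")
  invisible(x)
}

#' Derive the composition of a topology
#'
#' @param topology A [parse_topology()] result.
#' @return The [glycan_composition()] with node counts per residue class and
#'   the number of sulfated sites.
#' @export
topology_composition <- function(topology) {
  stopifnot(inherits(topology, "glycan_topology"))
  cls <- topology$nodes$class
  glycan_composition(hex = sum(cls == "hex"), hexnac = sum(cls == "hexnac"),
                     dhex = sum(cls == "dhex"), neuac = sum(cls == "neuac"),
                     sulfo = sum(!is.na(topology$nodes$sulfo_pos)))
}

# ids of all nodes in the subtree rooted at `id` (inclusive)
.subtree_ids <- function(nodes, id) {
  out <- id
  frontier <- id
  while (length(frontier)) {
    kids <- nodes$id[nodes$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  sort(out)
}

# longest path (in residues) from any leaf of the subtree to its root
.subtree_depth <- function(nodes, id) {
  kids <- nodes$id[nodes$parent == id]
  if (!length(kids)) return(1L)
  1L + max(vapply(kids, function(k) .subtree_depth(nodes, k), integer(1)))
}

# summed permethylated residue mass of a node set, incl. sulfate deltas
.node_set_mass <- function(nodes, ids) {
  sel <- nodes[nodes$id %in% ids, ]
  mc <- .mass_const
  sum(c(hex = mc$hex, hexnac = mc$hexnac, dhex = mc$dhex,
        neuac = mc$neuac)[sel$class]) +
    sum(!is.na(sel$sulfo_pos)) * mc$sulfo
}
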