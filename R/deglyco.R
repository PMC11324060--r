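# Deglycosylation: iterative removal of terminal sugar rings prior to
# fragment analysis, so that glycosides are compared by their aglycones.
#
# A terminal sugar is detected structurally: a saturated 5- or 6-membered
# ring with exactly one ring oxygen, carrying at least two exocyclic
# hydroxyl groups on its ring carbons, and attached to the remainder of the
# molecule through a single O-glycosidic bond (ring carbon - exocyclic
# oxygen - aglycone). The glycosidic oxygen stays with the aglycone (as a
# hydroxyl); removal iterates so that oligosaccharide chains are pruned one
# terminal unit at a time.

# shortest ring through atom i (a ring oxygen candidate); returns atom ids
# or NULL when i is not in a ring of size <= max_size
.fg_smallest_ring_through <- function(mol, i, max_size = 6L) {
  g <- fg_graph(mol)
  nb_bonds <- which((mol$bonds$a == i | mol$bonds$b == i) & mol$ring_bond)
  best <- NULL
  for (k in nb_bonds) {
    j <- if (mol$bonds$a[k] == i) mol$bonds$b[k] else mol$bonds$a[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]]
    if (length(sp) == 0L) next
    ring <- as.integer(sp)
    if (length(ring) <= max_size && (is.null(best) || length(ring) < length(best))) {
      best <- ring
    }
  }
  best
}

.fg_neighbors <- function(mol, i) {
  c(mol$bonds$b[mol$bonds$a == i], mol$bonds$a[mol$bonds$b == i])
}

# locate one terminal sugar; returns list(sugar_atoms, cut_bond=c(ringC, O))
# or NULL
.fg_find_terminal_sugar <- function(mol) {
  ring_oxygens <- which(mol$elem == "O" & mol$ring_atom & !mol$arom)
  for (o in ring_oxygens) {
    ring <- .fg_smallest_ring_through(mol, o, max_size = 6L)
    if (is.null(ring) || !(length(ring) %in% c(5L, 6L))) next
    others <- setdiff(ring, o)
    if (!all(mol$elem[others] == "C") || any(mol$arom[ring])) next
    if (sum(mol$elem[ring] == "O") != 1L) next
    # ring bonds must all be single
    rb <- mol$bonds$a %in% ring & mol$bonds$b %in% ring & mol$ring_bond
    if (any(mol$bonds$order[rb] != 1L)) next
    # exocyclic hydroxyls on ring carbons
    n_oh <- 0L
    glyco <- list()
    for (cc in others) {
      for (nb in setdiff(.fg_neighbors(mol, cc), ring)) {
        if (mol$elem[nb] != "O") next
        deg <- mol$degree[nb]
        if (deg == 1L && mol$nh[nb] >= 1L) n_oh <- n_oh + 1L
        if (deg == 2L && !mol$ring_atom[nb]) {
          # candidate glycosidic oxygen: bonded onward to the aglycone
          ord <- mol$bonds$order[(mol$bonds$a == cc & mol$bonds$b == nb) |
                                 (mol$bonds$a == nb & mol$bonds$b == cc)]
          if (all(ord == 1L)) glyco[[length(glyco) + 1L]] <- c(cc, nb)
        }
      }
    }
    if (n_oh < 2L || length(glyco) == 0L) next
    for (gl in glyco) {
      cc <- gl[1]; ox <- gl[2]
      # cut the anomeric C - O bond; the component containing the ring carbon
      # is the sugar unit, which must be terminal: no ring atoms beyond this
      # ring, and a non-empty aglycone on the other side
      g <- fg_graph(mol)
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(cc, ox)))
      memb <- igraph::components(g2)$membership
      sugar_side <- which(memb == memb[cc])
      if (memb[ox] == memb[cc]) next        # bond was in a ring, not glycosidic
      ring_in_sugar <- sugar_side[mol$ring_atom[sugar_side]]
      if (!all(ring_in_sugar %in% ring)) next
      if (length(sugar_side) >= mol$n_atoms) next
      return(list(sugar_atoms = sugar_side, cut = gl))
    }
  }
  NULL
}

# graph-level deglycosylation; returns the (possibly unchanged) molecule
deglycosylate_mol <- function(mol) {
  repeat {
    hit <- .fg_find_terminal_sugar(mol)
    if (is.null(hit)) return(mol)
    keep <- setdiff(seq_len(mol$n_atoms), hit$sugar_atoms)
    if (length(keep) == 0L) return(mol)
    mol <- fg_subgraph(mol, keep)
  }
}

#' Remove terminal sugar rings from a structure
#'
#' Iteratively removes terminal sugar rings (saturated 5/6-membered rings
#' with one ring oxygen and at least two exocyclic hydroxyls, attached via a
#' single O-glycosidic bond); the glycosidic oxygen remains on the aglycone.
#' Molecules without such sugars are returned unchanged (up to
#' canonicalization).
#'
#' @param smiles A SMILES string in aromatic (canonical) form.
#' @return The canonical SMILES of the aglycone.
#' @examples
#' \dontrun{
#' deglycosylate("OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O")  # salicin -> saligenin
#' }
#' @export
deglycosylate <- function(smiles) {
  mol <- deglycosylate_mol(mol_from_smiles(smiles))
  out <- ob_canonical_smiles(mol_to_smiles(mol), strip_stereo = TRUE)
  if (is.na(out)) stop("canonicalization of deglycosylated structure failed")
  out
}
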