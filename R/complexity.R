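# Spatial score (SPS) and its heavy-atom-normalized form (nSPS).
#
# Every heavy atom contributes h * s * r * n^2:
#   h: hybridization term (sp 1, sp2 2, sp3 3, other 4)
#   s: stereo term (2 for potential stereocenters and atoms of potential
#      E/Z double bonds, else 1)
#   r: ring term (2 for non-aromatic ring atoms, else 1)
#   n: number of heavy-atom neighbors
# SPS is the sum over heavy atoms; nSPS divides by the heavy-atom count.
# The term scheme and constants follow the published spatial-score
# descriptor; the pipeline computes it on standardized racemic structures,
# where stereogenicity is perceived as *potential* stereocenters/bonds.
#
# Hybridization is assigned from electron domains (sigma bonds + implicit
# hydrogens + lone pairs), with aromatic atoms sp2 and lone-pair N/O
# promoted to sp2 when conjugated to an aromatic system or to a
# multiply-bonded C/N neighbor. Stereo perception uses Weisfeiler-Lehman
# symmetry classes: a tetrahedral candidate is stereogenic when its four
# substituent slots fall into distinct classes of the refinement rooted at
# the candidate; candidates whose only degeneracy is one pair of
# symmetry-equivalent branches become stereogenic when those branches
# contain further stereogenic (or candidate) units, which covers
# para-stereocenters such as 1,4-disubstituted cyclohexanes.

.FG_VALENCE_ELECTRONS <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                           S = 6, Cl = 7, Se = 6, Br = 7, I = 7)

# Weisfeiler-Lehman refinement; returns integer class per atom. `root`
# (optional) is given a unique initial color.
.fg_wl_classes <- function(mol, root = NA_integer_) {
  n <- mol$n_atoms
  lab <- paste(mol$elem, mol$charge, as.integer(mol$arom), mol$degree, mol$nh)
  if (!is.na(root)) lab[root] <- paste(lab[root], "ROOT")
  cls <- match(lab, unique(lab))
  nbrs <- vector("list", n)
  bord <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
    nbrs[[a]] <- c(nbrs[[a]], b); bord[[a]] <- c(bord[[a]], o)
    nbrs[[b]] <- c(nbrs[[b]], a); bord[[b]] <- c(bord[[b]], o)
  }
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      if (length(nbrs[[i]]) == 0L) return(as.character(cls[i]))
      nb <- paste(bord[[i]], cls[nbrs[[i]]], sep = "/")
      paste(cls[i], paste(sort(nb), collapse = ","))
    }, character(1))
    new_cls <- match(sig, unique(sig))
    if (length(unique(new_cls)) == length(unique(cls))) return(new_cls)
    cls <- new_cls
  }
}

# per-atom multiple-bond summary (non-aromatic orders)
.fg_bond_orders_at <- function(mol) {
  n <- mol$n_atoms
  out <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
    out[[a]] <- c(out[[a]], o); out[[b]] <- c(out[[b]], o)
  }
  out
}

# hybridization classes: "sp", "sp2", "sp3", "other"
.fg_hybridization <- function(mol) {
  n <- mol$n_atoms
  ords <- .fg_bond_orders_at(mol)
  hyb <- character(n)
  for (i in seq_len(n)) {
    if (mol$arom[i]) { hyb[i] <- "sp2"; next }
    ve <- .FG_VALENCE_ELECTRONS[[mol$elem[i]]]
    if (is.null(ve) || is.na(ve)) { hyb[i] <- "other"; next }
    ve <- ve - mol$charge[i]
    bond_sum <- sum(ords[[i]]) + mol$nh[i]
    lp <- max(0, floor((ve - bond_sum) / 2))
    domains <- mol$degree[i] + mol$nh[i] + lp
    hyb[i] <- if (domains <= 2L) "sp" else if (domains == 3L) "sp2"
              else if (domains == 4L) "sp3" else "other"
  }
  # conjugation promotion for lone-pair N/O with only single bonds
  nbrs <- lapply(seq_len(n), function(i) .fg_neighbors(mol, i))
  has_multi <- vapply(seq_len(n), function(i) any(ords[[i]] %in% c(2L, 3L)),
                      logical(1))
  for (i in seq_len(n)) {
    if (hyb[i] != "sp3" || !(mol$elem[i] %in% c("N", "O"))) next
    if (has_multi[i]) next
    for (j in nbrs[[i]]) {
      if (mol$arom[j] || (mol$elem[j] %in% c("C", "N") && has_multi[j])) {
        hyb[i] <- "sp2"; break
      }
    }
  }
  hyb
}

# potential tetrahedral stereocenters (indices), racemic perception
.fg_potential_stereocenters <- function(mol) {
  n <- mol$n_atoms
  ords <- .fg_bond_orders_at(mol)
  nbrs <- lapply(seq_len(n), function(i) .fg_neighbors(mol, i))
  candidate <- logical(n)
  for (i in seq_len(n)) {
    if (mol$arom[i]) next
    el <- mol$elem[i]; d <- mol$degree[i]; h <- mol$nh[i]
    multi <- any(ords[[i]] %in% c(2L, 3L))
    if (el %in% c("C", "Si")) {
      candidate[i] <- !multi && ((d == 4L && h == 0L) || (d == 3L && h == 1L))
    } else if (el %in% c("N", "P") && d == 4L && h == 0L) {
      candidate[i] <- TRUE                      # quaternary / phosphonium
    } else if (el == "P" && d == 3L && h == 0L && !multi) {
      candidate[i] <- TRUE                      # phosphine, lone pair as slot
    } else if (el == "S" && d == 3L && h == 0L &&
               sum(ords[[i]] == 2L) == 1L) {
      candidate[i] <- TRUE                      # sulfoxide-like S(IV)
    }
  }
  if (!any(candidate)) return(integer(0))
  resolved <- logical(n)
  eq_pair_nbrs <- vector("list", n)
  for (i in which(candidate)) {
    cls <- .fg_wl_classes(mol, root = i)
    ncls <- cls[nbrs[[i]]]
    dup <- duplicated(ncls) | duplicated(ncls, fromLast = TRUE)
    if (!any(dup)) {
      resolved[i] <- TRUE
    } else if (sum(dup) == 2L) {
      eq_pair_nbrs[[i]] <- nbrs[[i]][dup]       # exactly one equivalent pair
    }
  }
  # dependent (para) stereocenters: an unresolved candidate with one
  # equivalent branch pair becomes stereogenic when the branch contains
  # another stereogenic unit or candidate
  stereo_bond_atoms <- .fg_potential_stereo_bond_atoms(mol)
  g <- fg_graph(mol)
  repeat {
    changed <- FALSE
    for (i in which(candidate & !resolved)) {
      if (is.null(eq_pair_nbrs[[i]])) next
      g2 <- igraph::delete_vertices(g, i)
      vmap <- setdiff(seq_len(n), i)
      memb <- igraph::components(g2)$membership
      start <- match(eq_pair_nbrs[[i]][1], vmap)
      branch <- vmap[memb == memb[start]]
      interesting <- union(which(resolved | candidate), stereo_bond_atoms)
      if (any(setdiff(interesting, i) %in% branch)) {
        resolved[i] <- TRUE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  which(resolved)
}

# atoms belonging to potential E/Z double bonds
.fg_potential_stereo_bond_atoms <- function(mol) {
  sel <- which(mol$bonds$order == 2L)
  if (length(sel) == 0L) return(integer(0))
  cls <- .fg_wl_classes(mol)
  nbrs <- lapply(seq_len(mol$n_atoms), function(i) .fg_neighbors(mol, i))
  g <- fg_graph(mol)
  out <- integer(0)
  for (k in sel) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    if (mol$arom[a] || mol$arom[b]) next
    if (mol$ring_bond[k]) {
      # stereo only in large rings (>= 8 atoms)
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(a, b)))
      sp <- igraph::distances(g2, v = a, to = b)[1, 1]
      if (is.finite(sp) && sp + 1 < 8) next
    }
    end_ok <- function(x, partner) {
      subs <- setdiff(nbrs[[x]], partner)
      nh <- mol$nh[x]
      slots <- length(subs) + nh + if (mol$elem[x] == "N") 1L else 0L
      if (slots < 1L || length(subs) + nh > 2L) return(FALSE)
      if (length(subs) == 2L) return(cls[subs[1]] != cls[subs[2]])
      if (length(subs) == 0L) return(FALSE)
      nh <= 1L
    }
    if (end_ok(a, b) && end_ok(b, a)) out <- c(out, a, b)
  }
  unique(out)
}

#' Per-atom spatial score terms
#'
#' Returns the hybridization, stereo, ring and neighbor terms together with
#' each atom's contribution to the spatial score.
#'
#' @param molecule Standardized SMILES or `fg_mol`.
#' @return A data.frame with one row per heavy atom: `elem`, `hyb`,
#'   `h_term`, `s_term`, `r_term`, `n_term` and `score` (= h*s*r*n^2).
#' @export
atom_spatial_score <- function(molecule) {
  mol <- if (inherits(molecule, "fg_mol")) molecule else mol_from_smiles(molecule)
  if (mol$n_atoms < 1L) stop("molecule has no heavy atoms")
  hyb <- .fg_hybridization(mol)
  h_term <- c(sp = 1, sp2 = 2, sp3 = 3, other = 4)[hyb]
  stereo_atoms <- union(.fg_potential_stereocenters(mol),
                        .fg_potential_stereo_bond_atoms(mol))
  s_term <- ifelse(seq_len(mol$n_atoms) %in% stereo_atoms, 2, 1)
  r_term <- ifelse(mol$ring_atom & !mol$arom, 2, 1)
  n_term <- mol$degree
  data.frame(elem = mol$elem, hyb = hyb, h_term = unname(h_term),
             s_term = s_term, r_term = r_term, n_term = n_term,
             score = unname(h_term) * s_term * r_term * n_term^2,
             stringsAsFactors = FALSE)
}

#' Spatial score (SPS) and normalized spatial score (nSPS)
#'
#' The spatial score sums, over all heavy atoms, the product of
#' hybridization, stereo, ring and squared-neighbor-count terms; nSPS is the
#' score divided by the number of heavy atoms. Both are invariant to atom
#' ordering and SMILES rendering. Intended for standardized (racemic)
#' structures: stereo terms reflect potential stereocenters.
#'
#' @param molecule Standardized SMILES or `fg_mol` (a single connected,
#'   standardized structure).
#' @return A list with `sps` and `nsps`.
#' @examples
#' \dontrun{
#' nsps("c1ccccc1")      # benzene: sps 48, nsps 8
#' }
#' @export
nsps <- function(molecule) {
  terms <- atom_spatial_score(molecule)
  sps <- sum(terms$score)
  list(sps = sps, nsps = sps / nrow(terms))
}
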