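# Lightweight molecular graph model used by all fragment-combination logic.
#
# Molecules are stored as plain atom/bond tables ("fg_mol" objects) parsed
# from aromatic-form SMILES as written by Open Babel's canonical writer.
# Structure standardization always goes through Open Babel first (see
# ob_canonical_smiles()), so this parser only needs to cover the canonical
# dialect: organic subset + bracket atoms, branches, ring closures (incl.
# %nn), charges, and aromatic lowercase atoms. Stereo markers are accepted
# and discarded (the whole pipeline works on racemic structures).

.FG_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.FG_AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s", "se", "as")

# default valence lists used for implicit hydrogen perception (SMILES rules)
.FG_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

# average atomic masses for the elements the pipeline encounters
.FG_MASSES <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974, S = 32.065,
  Cl = 35.453, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Cu = 63.546, Zn = 65.380, As = 74.922, Se = 78.971, Br = 79.904,
  Ag = 107.868, Sn = 118.710, I = 126.904, Pt = 195.084, Au = 196.967
)

#' Parse a SMILES string into a molecular graph
#'
#' Builds an `fg_mol` object (atom and bond tables plus derived per-atom
#' annotations) from an aromatic-form SMILES string. Tetrahedral and
#' double-bond stereo descriptors are silently dropped: the package operates
#' on racemic structures throughout. Unannotated bonds between two aromatic
#' atoms are read as aromatic and subsequently demoted to single bonds when
#' they are not part of a ring (biaryl linkages), matching the conventions of
#' Open Babel's canonical SMILES writer.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `fg_mol`: a list with elements `elem`, `arom`,
#'   `charge`, `nh` (total hydrogen count per atom), `bonds` (data.frame with
#'   columns `a`, `b`, `order`; order 4 denotes an aromatic bond), `ring_atom`,
#'   `ring_bond`, `degree`, `mw`, `n_atoms` (heavy-atom count) and `n_rings`
#'   (cyclomatic number).
#' @examples
#' m <- mol_from_smiles("c1ccncc1")
#' m$n_atoms
#' m$n_rings
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES")

  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hexp <- integer(0)  # explicit H from bracket atoms, NA when implicit
  ba <- integer(0); bb <- integer(0); bo <- integer(0)

  prev <- NA_integer_
  pending <- NA_integer_     # explicit bond order waiting for next atom
  stack <- integer(0)
  ring_open <- list()        # closure label -> c(atom, order or NA)

  add_atom <- function(sym, aromatic, chg, h) {
    elem[[length(elem) + 1L]] <<- sym
    arom[[length(arom) + 1L]] <<- aromatic
    charge[[length(charge) + 1L]] <<- chg
    hexp[[length(hexp) + 1L]] <<- h
    idx <- length(elem)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom[prev] && aromatic) 4L else 1L
      ba[[length(ba) + 1L]] <<- prev; bb[[length(bb) + 1L]] <<- idx
      bo[[length(bo) + 1L]] <<- ord
    }
    prev <<- idx
    pending <<- NA_integer_
    idx
  }

  close_ring <- function(lab) {
    key <- as.character(lab)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- c(prev, pending)
      pending <<- NA_integer_
    } else {
      open <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      ord <- pending
      if (is.na(ord)) ord <- open[2]
      if (is.na(ord)) ord <- if (arom[open[1]] && arom[prev]) 4L else 1L
      ba[[length(ba) + 1L]] <<- open[1]; bb[[length(bb) + 1L]] <<- prev
      bo[[length(bo) + 1L]] <<- ord
      pending <<- NA_integer_
    }
  }

  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom in SMILES: ", smiles)
      content <- substr(s, i + 1L, i + j - 2L)
      i <- i + j
      m <- regmatches(content, regexec(
        "^([0-9]*)([A-Z][a-z]?|as|se|b|c|n|o|p|s)(@{0,2})(TH[12]|AL[12]|SP[1-3])?(H[0-9]*)?([+-]+[0-9]*|)?(:[0-9]+)?$",
        content))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", content, "]")
      sym <- m[3]
      aromatic <- sym %in% .FG_AROMATIC_ELEMS
      if (aromatic) {
        sym <- if (nchar(sym) == 1L) toupper(sym) else
          paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2))
      }
      if (!(sym %in% c(names(.FG_MASSES), "H"))) {
        stop("unknown element '", sym, "' in SMILES: ", smiles)
      }
      h <- 0L
      if (nzchar(m[6])) {
        h <- if (m[6] == "H") 1L else as.integer(substr(m[6], 2, nchar(m[6])))
      }
      chg <- 0L
      if (nzchar(m[7])) {
        sgn <- if (substr(m[7], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[7])
        chg <- if (nzchar(digits)) sgn * as.integer(digits)
               else sgn * nchar(gsub("[0-9]", "", m[7]))
      }
      add_atom(sym, aromatic, chg, h)
    } else if (ch %in% c("C", "B") && i < n && substr(s, i + 1L, i + 1L) %in% c("l", "r") &&
               substr(s, i, i + 1L) %in% c("Cl", "Br")) {
      add_atom(substr(s, i, i + 1L), FALSE, 0L, NA_integer_)
      i <- i + 2L
    } else if (ch %in% .FG_ORGANIC) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch == "-") { pending <- 1L; i <- i + 1L
    } else if (ch == "=") { pending <- 2L; i <- i + 1L
    } else if (ch == "#") { pending <- 3L; i <- i + 1L
    } else if (ch == ":") { pending <- 4L; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pending <- 1L; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parentheses in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "%") {
      lab <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", lab)) stop("bad %nn ring closure in SMILES: ", smiles)
      close_ring(as.integer(lab)); i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_integer_; i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(stack) > 0L) stop("unbalanced parentheses in SMILES: ", smiles)
  if (length(elem) == 0L) stop("no atoms parsed from SMILES: ", smiles)

  mol <- list(elem = elem, arom = arom, charge = charge, hexp = hexp,
              bonds = data.frame(a = ba, b = bb, order = bo))
  # fold explicit-hydrogen atoms into their heavy neighbor's H count
  hs <- which(mol$elem == "H")
  if (length(hs) > 0L) mol <- .fg_fold_hydrogens(mol, hs)
  .fg_finalize(mol)
}

.fg_fold_hydrogens <- function(mol, hs) {
  for (h in hs) {
    nb <- c(mol$bonds$b[mol$bonds$a == h], mol$bonds$a[mol$bonds$b == h])
    if (length(nb) == 1L) {
      if (is.na(mol$hexp[nb])) mol$hexp[nb] <- 0L
      mol$hexp[nb] <- mol$hexp[nb] + 1L
    }
  }
  keep <- setdiff(seq_along(mol$elem), hs)
  remap <- match(seq_along(mol$elem), keep)
  bonds <- mol$bonds[mol$bonds$a %in% keep & mol$bonds$b %in% keep, , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  list(elem = mol$elem[keep], arom = mol$arom[keep], charge = mol$charge[keep],
       hexp = mol$hexp[keep], bonds = bonds)
}

# Implicit hydrogen count under SMILES default-valence rules. Aromatic
# carbons contribute one pi bond beyond their sigma framework; aromatic
# nitrogen/phosphorus only when pyridine-like (two ring connections, no
# exocyclic multiple bond); aromatic O/S donate a lone pair instead.
.fg_implicit_h <- function(elem, arom, ords) {
  bsum <- sum(ifelse(ords == 4L, 1L, ords))
  if (arom) {
    incr <- if (elem == "C") 1L
            else if (elem %in% c("N", "P") && length(ords) == 2L && !any(ords %in% c(2L, 3L))) 1L
            else 0L
    bsum <- bsum + incr
  }
  vals <- .FG_VALENCES[[elem]]
  if (is.null(vals)) return(0L)
  val <- vals[vals >= bsum][1]
  if (is.na(val)) 0L else as.integer(val - bsum)
}

# derive ring perception, implicit hydrogens, degrees and mass
.fg_finalize <- function(mol) {
  n <- length(mol$elem)
  bonds <- mol$bonds
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0L) g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))

  ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  # demote aromatic-labelled bonds outside rings (biaryl single bonds)
  demote <- bonds$order == 4L & !ring_bond
  bonds$order[demote] <- 1L

  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) ring_atom[unique(c(bonds$a[ring_bond], bonds$b[ring_bond]))] <- TRUE
  # an atom marked aromatic must sit in an aromatic ring; isolated lowercase
  # atoms (not expected from the canonical writer) are kept as written

  degree <- tabulate(c(bonds$a, bonds$b), nbins = n)

  nh <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(mol$hexp[i])) { nh[i] <- mol$hexp[i]; next }
    ords <- c(bonds$order[bonds$a == i], bonds$order[bonds$b == i])
    nh[i] <- .fg_implicit_h(mol$elem[i], mol$arom[i], ords)
  }

  mass <- .FG_MASSES[mol$elem]
  if (anyNA(mass)) {
    warning("unknown atomic mass for element(s): ",
            paste(unique(mol$elem[is.na(mass)]), collapse = ", "))
    mass[is.na(mass)] <- 0
  }
  mw <- sum(mass) + sum(nh) * .FG_MASSES[["H"]]

  comps <- igraph::components(g)$no
  structure(list(
    elem = mol$elem, arom = mol$arom, charge = mol$charge, nh = nh,
    bonds = bonds, ring_atom = ring_atom, ring_bond = ring_bond,
    degree = degree, mw = unname(mw), n_atoms = n,
    n_rings = nrow(bonds) - n + comps, n_components = comps
  ), class = "fg_mol")
}

#' @export
print.fg_mol <- function(x, ...) {
  cat(sprintf("<fg_mol> %d heavy atoms, %d bonds, %d ring(s), MW %.1f\n",
              x$n_atoms, nrow(x$bonds), x$n_rings, x$mw))
  invisible(x)
}

# igraph view of the heavy-atom skeleton
fg_graph <- function(mol) {
  g <- igraph::make_empty_graph(mol$n_atoms, directed = FALSE)
  if (nrow(mol$bonds) > 0L) g <- igraph::add_edges(g, rbind(mol$bonds$a, mol$bonds$b))
  g
}

# restrict a molecule to a subset of atoms (1-based indices), keeping bonds
# with both ends retained; hydrogen counts of cut atoms grow implicitly on
# re-finalization only for bracket-free atoms, so we recompute hexp as NA
# except where the original atom carried an explicit count.
fg_subgraph <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  stopifnot(all(keep >= 1L), all(keep <= mol$n_atoms))
  remap <- match(seq_len(mol$n_atoms), keep)
  bonds <- mol$bonds[mol$bonds$a %in% keep & mol$bonds$b %in% keep, c("a", "b", "order")]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  # atoms cut free from an aromatic ring can no longer be aromatic if they
  # lost all their aromatic bonds
  arom <- mol$arom[keep]
  if (nrow(bonds) > 0L) {
    has_ar <- rep(FALSE, length(keep))
    sel <- bonds$order == 4L
    has_ar[unique(c(bonds$a[sel], bonds$b[sel]))] <- TRUE
    arom <- arom & has_ar
  } else arom[] <- FALSE
  .fg_finalize(list(elem = mol$elem[keep], arom = arom, charge = mol$charge[keep],
                    hexp = rep(NA_integer_, length(keep)), bonds = bonds))
}

# connected components of a molecule as a list of atom-index vectors
fg_components <- function(mol) {
  comp <- igraph::components(fg_graph(mol))$membership
  split(seq_len(mol$n_atoms), comp)
}

#' Write a molecular graph back to SMILES
#'
#' Serializes an `fg_mol` to a (non-canonical) SMILES string; callers that
#' need a canonical form pass the result through [ob_canonical_smiles()].
#' Aromatic atoms are written lowercase, single bonds between two aromatic
#' atoms are written explicitly as `-`, and atoms are bracketed whenever
#' charge or a non-default hydrogen count requires it.
#'
#' @param mol An `fg_mol` object.
#' @return A SMILES string.
#' @export
mol_to_smiles <- function(mol) {
  n <- mol$n_atoms
  if (n == 0L) stop("empty molecule")
  bonds <- mol$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, bonds$order[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, bonds$order[k]))
  }

  atom_token <- function(i) {
    el <- mol$elem[i]
    need_bracket <- mol$charge[i] != 0L || !(el %in% .FG_ORGANIC)
    if (!need_bracket) {
      # check that implicit-H perception would reproduce the stored H count
      ords <- if (is.null(adj[[i]])) integer(0) else adj[[i]][, 2]
      himp <- .fg_implicit_h(el, mol$arom[i], ords)
      if (himp != mol$nh[i]) need_bracket <- TRUE
    }
    sym <- if (mol$arom[i]) tolower(el) else el
    if (!need_bracket) return(sym)
    h <- mol$nh[i]
    htxt <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    chg <- mol$charge[i]
    ctxt <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
            else sprintf("%+d", chg)
    paste0("[", sym, htxt, ctxt, "]")
  }

  bond_token <- function(i, j, ord) {
    if (ord == 2L) return("=")
    if (ord == 3L) return("#")
    if (ord == 4L) return(if (mol$arom[i] && mol$arom[j]) "" else ":")
    if (mol$arom[i] && mol$arom[j]) "-" else ""
  }

  smiles_parts <- character(0)
  for (comp in fg_components(mol)) {
    env <- new.env()
    env$out <- character(0)
    write_atom_with_closures(comp[1], mol, adj, bonds, atom_token, bond_token,
                             emit_env = env)
    smiles_parts <- c(smiles_parts, paste0(env$out, collapse = ""))
  }
  paste0(smiles_parts, collapse = ".")
}

# The recursive writer: emits SMILES for the component containing `start`.
# Ring-closure digits are attached to the first-visited atom lazily by
# rewriting the output buffer, which keeps the algorithm single-pass.
write_atom_with_closures <- function(start, mol, adj, bonds, atom_token,
                                     bond_token, emit_env) {
  visited <- rep(FALSE, mol$n_atoms)
  used <- rep(FALSE, nrow(bonds))
  atom_pos <- integer(mol$n_atoms)   # index in `out` where atom token sits
  next_label <- 0L
  edge_id <- function(a, b) which((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))[1]

  rec <- function(i, parent_edge) {
    visited[i] <<- TRUE
    emit_env$out[[length(emit_env$out) + 1L]] <- atom_token(i)
    atom_pos[i] <<- length(emit_env$out)
    nbrs <- adj[[i]]
    if (is.null(nbrs)) return(invisible())
    branches <- list()
    for (k in seq_len(nrow(nbrs))) {
      j <- nbrs[k, 1]; ord <- nbrs[k, 2]
      eid <- edge_id(i, j)
      if (used[eid]) next
      if (visited[j]) {
        used[eid] <<- TRUE
        next_label <<- next_label + 1L
        lab <- if (next_label > 9L) paste0("%", sprintf("%02d", next_label)) else as.character(next_label)
        btok <- bond_token(i, j, ord)
        # append digit to the earlier atom's token
        emit_env$out[[atom_pos[j]]] <- paste0(emit_env$out[[atom_pos[j]]], btok, lab)
        emit_env$out[[length(emit_env$out) + 1L]] <- paste0(btok, lab)
      } else {
        branches[[length(branches) + 1L]] <- c(j, ord, eid)
      }
    }
    if (length(branches) == 0L) return(invisible())
    for (k in seq_along(branches)) {
      j <- branches[[k]][1]; ord <- branches[[k]][2]; eid <- branches[[k]][3]
      if (used[eid] || visited[j]) next
      used[eid] <<- TRUE
      remaining <- if (k < length(branches))
        any(vapply(branches[seq(k + 1L, length(branches))],
                   function(t) !visited[t[1]], logical(1))) else FALSE
      if (remaining) emit_env$out[[length(emit_env$out) + 1L]] <- "("
      emit_env$out[[length(emit_env$out) + 1L]] <- bond_token(i, j, ord)
      rec(j, eid)
      if (remaining) emit_env$out[[length(emit_env$out) + 1L]] <- ")"
    }
    invisible()
  }
  rec(start, NA_integer_)
  invisible()
}
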