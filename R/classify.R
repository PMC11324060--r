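# Fragment matching and the fusion/connection taxonomy.
#
# Matching maps every catalog fragment onto a molecule by labelled subgraph
# monomorphism. Molecule and fragment are expanded into bipartite
# atom/bond-vertex graphs (each bond becomes a vertex labelled with its
# order) so that igraph's LAD matcher can enforce element, charge,
# aromaticity and bond-order compatibility through per-vertex domains.
#
# Every unordered pair of retained hits is then typed:
#   shared atoms k >= 1 -> fusion family:
#     containment -> ffs (discard the contained hit)
#     k == 1 -> fs (spiro), k == 2 bonded -> fe (edge), 3 <= k <= 5 -> fb
#     (bridge), otherwise ffo (overlap artifact, discarded)
#   k == 0 -> connection family via linker paths through atoms external to
#     both hits: shortest path > cutoff -> cfc (no edge); 1 attachment pair
#     -> cm (monopodal); 2 -> bipodal, subtyped cbs (shared attachment
#     atom), cbe (adjacent attachment atoms on both fragments), cbb
#     (otherwise); >= 3 -> ct (tripodal and higher).

.FG_DISCARD_CODES <- c("ffs", "ffo", "cfc")
.FG_EDGE_CODES <- c("fs", "fe", "fb", "cm", "cbs", "cbe", "cbb", "ct")

# atom/bond expanded graph for labelled matching
.fg_expanded_graph <- function(mol) {
  na <- mol$n_atoms; nb <- nrow(mol$bonds)
  g <- igraph::make_empty_graph(na + nb, directed = FALSE)
  if (nb > 0L) {
    el <- rbind(cbind(mol$bonds$a, na + seq_len(nb)),
                cbind(mol$bonds$b, na + seq_len(nb)))
    g <- igraph::add_edges(g, t(el))
  }
  labels <- c(paste0(mol$elem, ":", mol$charge, ":", as.integer(mol$arom)),
              paste0("bond", mol$bonds$order))
  list(g = g, labels = labels, n_atoms = na)
}

#' Prepare a catalog for repeated matching
#'
#' Parses every catalog fragment once into the internal matching
#' representation. Passing the returned index to [find_fragment_hits()] or
#' [molecule_fcgs()] avoids re-parsing the catalog per molecule.
#'
#' @param catalog A catalog from [build_catalog()] or [read_catalog()].
#' @return An opaque index object.
#' @export
fg_catalog_index <- function(catalog) {
  idx <- lapply(seq_len(nrow(catalog)), function(i) {
    mol <- mol_from_smiles(catalog$smiles[i])
    c(list(frag_id = catalog$frag_id[i], mol = mol), .fg_expanded_graph(mol))
  })
  structure(idx, class = "fg_catalog_index")
}

#' Find all catalog fragment hits in a molecule
#'
#' Returns every substructure match of every catalog fragment as a hit;
#' symmetry-equivalent matches onto the same atom set are collapsed, so each
#' (fragment, atom set) pair appears once. Hits contained inside hits of
#' other fragments are retained here and resolved during pair
#' classification.
#'
#' @param molecule A standardized SMILES string or an `fg_mol`.
#' @param catalog A fragment catalog.
#' @param index Optional [fg_catalog_index()] for `catalog`.
#' @return A data.frame with columns `frag_id`, `occurrence` (0-based among
#'   matches of the same fragment) and a list column `atoms` of molecule
#'   atom indices.
#' @export
find_fragment_hits <- function(molecule, catalog, index = NULL) {
  mol <- if (inherits(molecule, "fg_mol")) molecule else mol_from_smiles(molecule)
  if (is.null(index)) index <- fg_catalog_index(catalog)
  tg <- .fg_expanded_graph(mol)
  frag_id <- integer(0); occurrence <- integer(0); atoms <- list()
  for (pat in index) {
    if (pat$mol$n_atoms > mol$n_atoms) next
    doms <- lapply(pat$labels, function(lb) which(tg$labels == lb))
    if (any(lengths(doms) == 0L)) next
    maps <- tryCatch(
      igraph::subgraph_isomorphisms(pat$g, tg$g, method = "lad",
                                    induced = FALSE, domains = doms),
      error = function(e) list())
    if (length(maps) == 0L) next
    sets <- unique(lapply(maps, function(m) sort(as.integer(m[seq_len(pat$n_atoms)]))))
    for (k in seq_along(sets)) {
      frag_id <- c(frag_id, pat$frag_id)
      occurrence <- c(occurrence, k - 1L)
      atoms[[length(atoms) + 1L]] <- sets[[k]]
    }
  }
  out <- data.frame(frag_id = frag_id, occurrence = occurrence)
  out$atoms <- atoms
  out
}

# distance matrix between two atom sets through external atoms only;
# entries are path lengths in bonds (Inf when no external path exists)
.fg_bridge_distances <- function(mol, atoms_a, atoms_b) {
  ext <- setdiff(seq_len(mol$n_atoms), c(atoms_a, atoms_b))
  g <- fg_graph(mol)
  nbrs <- lapply(seq_len(mol$n_atoms), function(i) .fg_neighbors(mol, i))
  d_ext <- NULL
  if (length(ext) > 0L) {
    sub <- igraph::induced_subgraph(g, ext)
    d_ext <- igraph::distances(sub)
    rownames(d_ext) <- colnames(d_ext) <- as.character(ext)
  }
  d <- matrix(Inf, nrow = length(atoms_a), ncol = length(atoms_b),
              dimnames = list(as.character(atoms_a), as.character(atoms_b)))
  for (ii in seq_along(atoms_a)) {
    x <- atoms_a[ii]
    ext_x <- intersect(nbrs[[x]], ext)
    for (jj in seq_along(atoms_b)) {
      y <- atoms_b[jj]
      if (y %in% nbrs[[x]]) d[ii, jj] <- 1
      if (!is.null(d_ext) && length(ext_x) > 0L) {
        ext_y <- intersect(nbrs[[y]], ext)
        if (length(ext_y) > 0L) {
          through <- 2 + min(d_ext[as.character(ext_x), as.character(ext_y)])
          d[ii, jj] <- min(d[ii, jj], through)
        }
      }
    }
  }
  d
}

#' Classify the combination type of two fragment hits
#'
#' Types the pairwise combination of two fragment occurrences in the same
#' molecule into the fusion/connection taxonomy (see the package overview).
#' The result is symmetric in the two hits.
#'
#' @param atoms_a,atoms_b Atom index sets of the two hits.
#' @param molecule SMILES string or `fg_mol` the hits belong to.
#' @param cutoff Maximum linker length in bonds for the connection family.
#' @return A single combination-type code: one of `fs`, `fe`, `fb`, `cm`,
#'   `cbs`, `cbe`, `cbb`, `ct`, or a discard code `ffs` (containment),
#'   `ffo` (overlap artifact), `cfc` (beyond cutoff).
#' @export
classify_pair <- function(atoms_a, atoms_b, molecule, cutoff = 3L) {
  mol <- if (inherits(molecule, "fg_mol")) molecule else mol_from_smiles(molecule)
  atoms_a <- sort(unique(as.integer(atoms_a)))
  atoms_b <- sort(unique(as.integer(atoms_b)))
  shared <- intersect(atoms_a, atoms_b)
  k <- length(shared)
  if (k >= 1L) {
    if (all(atoms_a %in% atoms_b) || all(atoms_b %in% atoms_a)) return("ffs")
    if (k == 1L) return("fs")
    if (k == 2L) {
      bonded <- any((mol$bonds$a == shared[1] & mol$bonds$b == shared[2]) |
                    (mol$bonds$a == shared[2] & mol$bonds$b == shared[1]))
      return(if (bonded) "fe" else "ffo")
    }
    if (k <= 5L) return("fb")
    return("ffo")
  }
  d <- .fg_bridge_distances(mol, atoms_a, atoms_b)
  if (!any(is.finite(d))) return("cfc")
  if (min(d) > cutoff) return("cfc")
  pairs <- which(d <= cutoff, arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 1L) return("cm")
  if (np >= 3L) return("ct")
  x1 <- atoms_a[pairs[1, 1]]; x2 <- atoms_a[pairs[2, 1]]
  y1 <- atoms_b[pairs[1, 2]]; y2 <- atoms_b[pairs[2, 2]]
  if (x1 == x2 || y1 == y2) return("cbs")
  bonded <- function(p, q) any((mol$bonds$a == p & mol$bonds$b == q) |
                               (mol$bonds$a == q & mol$bonds$b == p))
  if (bonded(x1, x2) && bonded(y1, y2)) return("cbe")
  "cbb"
}

#' Canonical signature of a fragment-combination graph
#'
#' Each edge is rendered `min(frag_id):max(frag_id):ctype` (occurrence
#' indices dropped), edge strings are sorted lexicographically and joined
#' with `|`. Identical molecular situations yield identical signatures
#' regardless of atom numbering or hit enumeration order.
#'
#' @param edges A data.frame with columns `frag_a`, `frag_b`, `ctype`.
#' @return A single signature string.
#' @export
canonical_signature <- function(edges) {
  if (nrow(edges) == 0L) return("")
  lo <- pmin(edges$frag_a, edges$frag_b)
  hi <- pmax(edges$frag_a, edges$frag_b)
  paste(sort(paste0(lo, ":", hi, ":", edges$ctype)), collapse = "|")
}

#' Assemble fragment-combination graphs from hits and typed edges
#'
#' Connected components (over hits) of the typed edge set with at least one
#' edge become FCGs; isolated hits yield no FCG.
#'
#' @param hits Hit table from [find_fragment_hits()].
#' @param edges Data.frame with columns `hit_a`, `hit_b` (row indices into
#'   `hits`), `frag_a`, `frag_b`, `ctype`; discard codes must already be
#'   excluded.
#' @return A list of FCGs, each a list with `hit_idx`, `edges`, `signature`.
#' @export
build_fcgs <- function(hits, edges) {
  if (nrow(edges) == 0L) return(list())
  stopifnot(!any(edges$ctype %in% .FG_DISCARD_CODES))
  g <- igraph::make_empty_graph(nrow(hits), directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$hit_a, edges$hit_b))
  memb <- igraph::components(g)$membership
  fcgs <- list()
  for (comp in sort(unique(memb))) {
    hit_idx <- which(memb == comp)
    sel <- edges$hit_a %in% hit_idx
    if (!any(sel)) next
    e <- edges[sel, , drop = FALSE]
    rownames(e) <- NULL
    fcgs[[length(fcgs) + 1L]] <- list(hit_idx = hit_idx, edges = e,
                                      signature = canonical_signature(e))
  }
  fcgs
}

#' Full fragment-combination analysis of one molecule
#'
#' Finds all catalog hits, discards hits contained in hits of other
#' fragments, types every remaining unordered pair, and assembles the typed
#' edges into fragment-combination graphs.
#'
#' @param molecule Standardized SMILES or `fg_mol`.
#' @param catalog Fragment catalog.
#' @param config An [fg_config()] (supplies the connection cutoff).
#' @param index Optional [fg_catalog_index()].
#' @return A list with `hits` (retained hits), `edges` (typed, discard codes
#'   excluded) and `fcgs` (list from [build_fcgs()]).
#' @export
molecule_fcgs <- function(molecule, catalog, config = fg_config(), index = NULL) {
  mol <- if (inherits(molecule, "fg_mol")) molecule else mol_from_smiles(molecule)
  hits <- find_fragment_hits(mol, catalog, index = index)
  empty_edges <- data.frame(hit_a = integer(0), hit_b = integer(0),
                            frag_a = integer(0), frag_b = integer(0),
                            ctype = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) < 1L) return(list(hits = hits, edges = empty_edges, fcgs = list()))
  # containment pass: drop hits strictly contained in a hit of another fragment
  n <- nrow(hits)
  drop <- rep(FALSE, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (hits$frag_id[i] == hits$frag_id[j]) next
        ai <- hits$atoms[[i]]; aj <- hits$atoms[[j]]
        if (length(ai) < length(aj) && all(ai %in% aj)) drop[i] <- TRUE
        if (length(aj) < length(ai) && all(aj %in% ai)) drop[j] <- TRUE
      }
    }
  }
  hits <- hits[!drop, , drop = FALSE]
  rownames(hits) <- NULL
  n <- nrow(hits)
  if (n < 2L) return(list(hits = hits, edges = empty_edges, fcgs = list()))
  ha <- integer(0); hb <- integer(0); ct <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ctype <- classify_pair(hits$atoms[[i]], hits$atoms[[j]], mol,
                             cutoff = config$connection_cutoff)
      if (ctype %in% .FG_DISCARD_CODES) next
      ha <- c(ha, i); hb <- c(hb, j); ct <- c(ct, ctype)
    }
  }
  edges <- data.frame(hit_a = ha, hit_b = hb,
                      frag_a = hits$frag_id[ha], frag_b = hits$frag_id[hb],
                      ctype = ct, stringsAsFactors = FALSE)
  list(hits = hits, edges = edges, fcgs = build_fcgs(hits, edges))
}

#' Fragment-combination analysis of a standardized library
#'
#' Runs [molecule_fcgs()] for every record that passed the structural
#' filters, under the per-molecule timeout, and returns one row per
#' (molecule, FCG). Timed-out or failed molecules are flagged in the
#' returned `failures` attribute and later classified NonPNP.
#'
#' @param records Standardized molecule table.
#' @param catalog Fragment catalog.
#' @param config An [fg_config()].
#' @return A data.frame (`fcg_table`) with columns `source_id`, `inchikey`,
#'   `fcg_index`, `signature`, `n_edges`, `edges` (semicolon-joined
#'   `fragA:fragB:ctype`). `attr(,"failures")` maps source_id to reason;
#'   `attr(,"n_hits")` maps source_id to its retained hit count.
#' @export
classify_library <- function(records, catalog, config = fg_config()) {
  index <- fg_catalog_index(catalog)
  todo <- which(records$passed_filters %in% TRUE & !is.na(records$smiles_std))
  res <- chunked_map(records$smiles_std[todo],
                     function(s) molecule_fcgs(s, catalog, config, index = index),
                     config)
  rows <- list()
  failures <- character(0)
  n_hits <- integer(0)
  for (k in seq_along(todo)) {
    i <- todo[k]
    r <- res[[k]]
    sid <- records$source_id[i]
    if (inherits(r, "fg_failure")) {
      failures[sid] <- if (inherits(r, "fg_timeout")) "timeout" else r$message
      next
    }
    n_hits[sid] <- nrow(r$hits)
    if (length(r$fcgs) == 0L) next
    for (fi in seq_along(r$fcgs)) {
      fcg <- r$fcgs[[fi]]
      e <- fcg$edges
      lo <- pmin(e$frag_a, e$frag_b); hi <- pmax(e$frag_a, e$frag_b)
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = sid, inchikey = records$inchikey[i], fcg_index = fi,
        signature = fcg$signature, n_edges = nrow(e),
        edges = paste(sort(paste0(lo, ":", hi, ":", e$ctype)), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(source_id = character(0), inchikey = character(0),
               fcg_index = integer(0), signature = character(0),
               n_edges = integer(0), edges = character(0),
               stringsAsFactors = FALSE)
  attr(out, "failures") <- failures
  attr(out, "n_hits") <- n_hits
  out
}
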