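# Synthetic test worlds with exact ground truth.
#
# The composer builds two-fragment molecules by explicit graph surgery so
# that the intended combination type is certain by construction: monopodal
# connections add a methylene linker, edge fusions merge a bond, spiro
# fusions merge an atom, bridge fusions merge a three-atom path, and
# bipodal-edge connections add two methylene linkers from adjacent atoms on
# each fragment. Requests that are not chemically realizable for a fragment
# pair (e.g. a spiro atom on an aromatic ring) return a skip signal rather
# than a silently wrong molecule.

#' Toy fragment catalog for tests and demonstrations
#'
#' Eight chemically distinct non-benzene ring scaffolds with stable
#' fragment ids. Deterministic; the seed argument exists for interface
#' symmetry with the other generators.
#'
#' @param seed Ignored (the catalog is fixed).
#' @return A catalog from [build_catalog()].
#' @export
make_toy_catalog <- function(seed = 0L) {
  build_catalog(c(
    "c1ccncc1",    # pyridine
    "C1CCNCC1",    # piperidine
    "C1CCNC1",     # pyrrolidine
    "C1COCCN1",    # morpholine
    "c1ccsc1",     # thiophene
    "c1ccoc1",     # furan
    "C1CCCC1",     # cyclopentane
    "C1CCCCCC1"    # cycloheptane
  ))
}

# ---- graph surgery helpers (raw atom/bond lists, finalized at the end) ----

.fg_raw <- function(mol) {
  list(elem = mol$elem, arom = mol$arom, charge = mol$charge,
       hexp = rep(NA_integer_, mol$n_atoms), bonds = mol$bonds)
}

# append molB to raw molA, merging B atoms listed in `merge` (matrix with
# columns b, a); returns list(raw, b_map)
.fg_combine <- function(rawA, molB, merge = NULL) {
  nA <- length(rawA$elem)
  merged_b <- if (is.null(merge)) integer(0) else merge[, 1]
  free_b <- setdiff(seq_len(molB$n_atoms), merged_b)
  b_map <- integer(molB$n_atoms)
  b_map[free_b] <- nA + seq_along(free_b)
  if (!is.null(merge)) b_map[merge[, 1]] <- merge[, 2]
  raw <- rawA
  raw$elem <- c(raw$elem, molB$elem[free_b])
  raw$arom <- c(raw$arom, molB$arom[free_b])
  raw$charge <- c(raw$charge, molB$charge[free_b])
  raw$hexp <- c(raw$hexp, rep(NA_integer_, length(free_b)))
  if (!is.null(merge)) {
    for (r in seq_len(nrow(merge))) {
      a <- merge[r, 2]
      raw$arom[a] <- raw$arom[a] || molB$arom[merge[r, 1]]
    }
  }
  for (k in seq_len(nrow(molB$bonds))) {
    a <- b_map[molB$bonds$a[k]]; b <- b_map[molB$bonds$b[k]]
    dup <- any((raw$bonds$a == a & raw$bonds$b == b) |
               (raw$bonds$a == b & raw$bonds$b == a))
    if (!dup) raw$bonds <- rbind(raw$bonds,
                                 data.frame(a = a, b = b, order = molB$bonds$order[k]))
  }
  list(raw = raw, b_map = b_map)
}

.fg_add_atom <- function(raw, elem, arom = FALSE) {
  raw$elem <- c(raw$elem, elem); raw$arom <- c(raw$arom, arom)
  raw$charge <- c(raw$charge, 0L); raw$hexp <- c(raw$hexp, NA_integer_)
  raw
}

.fg_add_bond <- function(raw, a, b, order = 1L) {
  raw$bonds <- rbind(raw$bonds, data.frame(a = a, b = b, order = order))
  raw
}

# first atom with >= min_h hydrogens (carbon preferred)
.fg_attach_atom <- function(mol, min_h = 1L, sp3_only = FALSE, degree_max = Inf) {
  cand <- which(mol$nh >= min_h & mol$degree <= degree_max &
                (!sp3_only | !mol$arom))
  pref <- cand[mol$elem[cand] == "C"]
  if (length(pref) > 0L) pref[1] else if (length(cand) > 0L) cand[1] else NA_integer_
}

# first fusable bond: both atoms carbon with >= 1 H, either both aromatic
# (aromatic bond) or both saturated (single ring bond)
.fg_fusable_bond <- function(mol, kind = c("any", "aromatic", "single")) {
  kind <- match.arg(kind)
  for (k in seq_len(nrow(mol$bonds))) {
    if (!mol$ring_bond[k]) next
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
    if (mol$elem[a] != "C" || mol$elem[b] != "C") next
    if (mol$nh[a] < 1L || mol$nh[b] < 1L) next
    if (o == 4L && mol$arom[a] && mol$arom[b] && kind %in% c("any", "aromatic")) {
      return(c(a, b, 4L))
    }
    if (o == 1L && !mol$arom[a] && !mol$arom[b] && kind %in% c("any", "single")) {
      return(c(a, b, 1L))
    }
  }
  NULL
}

# first saturated CH2-CH2-CH2 path along a ring (for bridge fusion)
.fg_bridge_path <- function(mol) {
  nbrs <- lapply(seq_len(mol$n_atoms), function(i) .fg_neighbors(mol, i))
  ok <- function(i, h) mol$elem[i] == "C" && !mol$arom[i] && mol$ring_atom[i] &&
    mol$degree[i] == 2L && mol$nh[i] >= h
  for (mid in seq_len(mol$n_atoms)) {
    if (!ok(mid, 2L)) next
    nb <- nbrs[[mid]]
    if (length(nb) != 2L) next
    if (ok(nb[1], 1L) && ok(nb[2], 1L)) {
      ords <- c(mol$bonds$order[(mol$bonds$a == mid & mol$bonds$b == nb[1]) |
                                (mol$bonds$b == mid & mol$bonds$a == nb[1])],
                mol$bonds$order[(mol$bonds$a == mid & mol$bonds$b == nb[2]) |
                                (mol$bonds$b == mid & mol$bonds$a == nb[2])])
      if (all(ords == 1L)) return(c(nb[1], mid, nb[2]))
    }
  }
  NULL
}

.fg_skip <- function(reason) structure(list(reason = reason), class = "fg_skip")

#' Is a composition result a skip signal?
#' @param x Result of [compose_molecule()].
#' @return `TRUE` for a skip signal.
#' @export
is_skip <- function(x) inherits(x, "fg_skip")

#' Compose a two-fragment molecule with a known combination type
#'
#' Joins two fragment structures so that the pair classifies as the
#' requested combination type by construction. Unrealizable requests (for
#' example a spiro fusion on an aromatic fragment) yield a skip signal
#' (test with [is_skip()]), never a silently wrong molecule.
#'
#' @param smiles_a,smiles_b Fragment SMILES (catalog entries).
#' @param ctype One of `"cm"`, `"fe"`, `"fs"`, `"fb"`, `"cbe"`.
#' @param frag_ids Optional integer pair recorded in the result.
#' @param catalog Optional catalog: when given, the composed molecule is
#'   additionally required to contain exactly the two intended fragment
#'   hits and nothing else (a bridge fusion can incidentally create a ring
#'   matching a third catalog fragment, which would falsify the ground
#'   truth; such compositions are skipped).
#' @return A list (`smiles`, `frag_ids`, `true_ctype`, `note`) or a skip
#'   signal.
#' @export
compose_molecule <- function(smiles_a, smiles_b, ctype, frag_ids = c(NA, NA),
                             catalog = NULL) {
  stopifnot(ctype %in% c("cm", "fe", "fs", "fb", "cbe"))
  molA <- mol_from_smiles(smiles_a)
  molB <- mol_from_smiles(smiles_b)
  rawA <- .fg_raw(molA)
  note <- NULL
  raw <- switch(ctype,
    cm = {
      a <- .fg_attach_atom(molA); b <- .fg_attach_atom(molB)
      if (is.na(a) || is.na(b)) return(.fg_skip("no attachment atom with free valence"))
      cmb <- .fg_combine(rawA, molB)
      r <- .fg_add_atom(cmb$raw, "C")
      link <- length(r$elem)
      r <- .fg_add_bond(r, a, link)
      r <- .fg_add_bond(r, link, cmb$b_map[b])
      note <- "methylene linker between one atom of each fragment"
      r
    },
    fe = {
      bA <- .fg_fusable_bond(molA, "any")
      if (is.null(bA)) return(.fg_skip("no fusable CH-CH bond in fragment A"))
      kind <- if (bA[3] == 4L) "aromatic" else "single"
      bB <- .fg_fusable_bond(molB, kind)
      if (is.null(bB)) return(.fg_skip("no bond of matching type in fragment B"))
      cmb <- .fg_combine(rawA, molB, merge = cbind(bB[1:2], bA[1:2]))
      note <- "fragments share one bond (edge fusion)"
      cmb$raw
    },
    fs = {
      a <- .fg_attach_atom(molA, min_h = 2L, sp3_only = TRUE, degree_max = 2L)
      b <- .fg_attach_atom(molB, min_h = 2L, sp3_only = TRUE, degree_max = 2L)
      if (is.na(a) || is.na(b) || !molA$ring_atom[a] %in% TRUE ||
          !molB$ring_atom[b] %in% TRUE) {
        return(.fg_skip("no saturated ring CH2 available for a spiro atom"))
      }
      cmb <- .fg_combine(rawA, molB, merge = cbind(b, a))
      note <- "fragments share one spiro atom"
      cmb$raw
    },
    fb = {
      pA <- .fg_bridge_path(molA); pB <- .fg_bridge_path(molB)
      if (is.null(pA) || is.null(pB)) {
        return(.fg_skip("no saturated three-carbon ring path for a bridge"))
      }
      cmb <- .fg_combine(rawA, molB, merge = cbind(pB, pA))
      note <- "fragments share a three-atom bridge"
      cmb$raw
    },
    cbe = {
      bA <- .fg_fusable_bond(molA, "any")
      bB <- .fg_fusable_bond(molB, "any")
      if (is.null(bA) || is.null(bB)) {
        return(.fg_skip("no adjacent CH-CH pair on both fragments"))
      }
      cmb <- .fg_combine(rawA, molB)
      r <- cmb$raw
      r <- .fg_add_atom(r, "C"); l1 <- length(r$elem)
      r <- .fg_add_bond(r, bA[1], l1); r <- .fg_add_bond(r, l1, cmb$b_map[bB[1]])
      r <- .fg_add_atom(r, "C"); l2 <- length(r$elem)
      r <- .fg_add_bond(r, bA[2], l2); r <- .fg_add_bond(r, l2, cmb$b_map[bB[2]])
      note <- "two methylene linkers from adjacent atoms on each fragment"
      r
    })
  mol <- .fg_finalize(raw)
  smi <- ob_canonical_smiles(mol_to_smiles(mol), strip_stereo = TRUE)
  if (is.na(smi)) return(.fg_skip("composed structure failed canonicalization"))
  if (!is.null(catalog)) {
    hits <- find_fragment_hits(smi, catalog)
    if (nrow(hits) != 2L ||
        !identical(sort(hits$frag_id), sort(as.integer(frag_ids)))) {
      return(.fg_skip("composition creates additional catalog fragment hits"))
    }
  }
  list(smiles = smi, frag_ids = frag_ids, true_ctype = ctype, note = note)
}

# append an n-carbon side chain (for generating distinct variants of one
# composition without touching its combination type)
.fg_append_chain <- function(smiles, len) {
  if (len == 0L) return(smiles)
  mol <- mol_from_smiles(smiles)
  a <- .fg_attach_atom(mol)
  if (is.na(a)) return(NA_character_)
  raw <- .fg_raw(mol)
  prev <- a
  for (k in seq_len(len)) {
    raw <- .fg_add_atom(raw, "C")
    raw <- .fg_add_bond(raw, prev, length(raw$elem))
    prev <- length(raw$elem)
  }
  ob_canonical_smiles(mol_to_smiles(.fg_finalize(raw)), strip_stereo = TRUE)
}

#' Enumerate all realizable two-fragment compositions of a catalog
#'
#' @param catalog A fragment catalog.
#' @param ctypes Combination types to attempt.
#' @return A data.frame: `frag_a`, `frag_b`, `ctype`, `smiles`,
#'   `signature`; skipped (unrealizable) combinations are absent.
#' @export
enumerate_compositions <- function(catalog,
                                   ctypes = c("cm", "fe", "fs", "fb", "cbe")) {
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    for (j in i:nrow(catalog)) {
      for (ct in ctypes) {
        res <- compose_molecule(catalog$smiles[i], catalog$smiles[j], ct,
                                frag_ids = c(catalog$frag_id[i], catalog$frag_id[j]),
                                catalog = catalog)
        if (is_skip(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          frag_a = catalog$frag_id[i], frag_b = catalog$frag_id[j], ctype = ct,
          smiles = res$smiles,
          signature = paste0(catalog$frag_id[i], ":", catalog$frag_id[j], ":", ct),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic compound library with known PNP statuses
#'
#' Builds a library of composed two-fragment molecules spanning all
#' realizable (pair, type) combinations of the toy catalog, plus
#' fragment-free decoys and acyclic filter failures. A seeded subset of the
#' base compositions is designated as the natural-product library, making
#' every record's downstream status (PNP / NPL / NP / NonPNP) known a
#' priori. Variants of one composition (alkyl side chains of increasing
#' length) share its fragment-combination signature but are distinct
#' compounds, which is what produces NPL records.
#'
#' @param n Library size (>= 10).
#' @param np_fraction Fraction of records designated as natural products.
#' @param seed Integer seed.
#' @param catalog Optional catalog (defaults to [make_toy_catalog()]).
#' @return A list: `library` (data.frame `source_id`, `smiles`,
#'   `true_status`, `signature`, `frag_a`, `frag_b`, `true_ctype`),
#'   `np_library` (data.frame `source_id`, `smiles`), `catalog`.
#' @export
make_synthetic_library <- function(n = 200L, np_fraction = 0.2, seed = 7L,
                                   catalog = NULL) {
  stopifnot(n >= 10L, np_fraction >= 0, np_fraction < 1)
  if (is.null(catalog)) catalog <- make_toy_catalog()
  comps <- enumerate_compositions(catalog)
  decoys <- data.frame(
    smiles = c("c1ccccc1", "Cc1ccncc1", "C1CCOC1", "CCO", "CCCCCCCCO"),
    why = c("benzene only (excluded fragment)", "single fragment hit",
            "ring without catalog fragment", "acyclic", "acyclic"),
    stringsAsFactors = FALSE)
  n_decoy <- max(4L, min(nrow(decoys), round(0.05 * n)))
  n_comp <- n - n_decoy
  # use at most half the records for distinct base compositions so that
  # side-chain variants (the NPL candidates) always exist
  n_base <- min(nrow(comps), max(1L, ceiling(n_comp / 2)))
  base_idx <- rep(seq_len(n_base), length.out = n_comp)
  variant <- (seq_len(n_comp) - 1L) %/% n_base
  smiles <- character(n_comp)
  for (k in seq_len(n_comp)) {
    smiles[k] <- .fg_append_chain(comps$smiles[base_idx[k]], variant[k])
  }
  lib <- data.frame(
    source_id = sprintf("syn%04d", seq_len(n_comp)),
    smiles = smiles,
    signature = comps$signature[base_idx],
    frag_a = comps$frag_a[base_idx], frag_b = comps$frag_b[base_idx],
    true_ctype = comps$ctype[base_idx],
    variant = variant, stringsAsFactors = FALSE)
  # drop any accidental structural duplicates (distinct variants should be
  # distinct molecules; guard regardless)
  lib <- lib[!duplicated(lib$smiles) & !is.na(lib$smiles), , drop = FALSE]
  # designate the NP library among the chain-free base records
  base_rows <- which(lib$variant == 0L)
  n_np <- min(length(base_rows), max(1L, round(np_fraction * nrow(lib))))
  np_rows <- .fg_with_seed(seed, sort(sample(base_rows, n_np)))
  np_sigs <- unique(lib$signature[np_rows])
  # guarantee at least one NPL record: some non-NP row must share an NP
  # signature
  has_npl <- any(!(seq_len(nrow(lib)) %in% np_rows) & lib$signature %in% np_sigs)
  if (!has_npl && any(lib$variant > 0L)) {
    first_var <- which(lib$variant > 0L)[1]
    base_of <- which(lib$variant == 0L &
                     lib$signature == lib$signature[first_var])[1]
    np_rows <- sort(union(np_rows, base_of))
    np_sigs <- unique(lib$signature[np_rows])
  }
  lib$true_status <- ifelse(seq_len(nrow(lib)) %in% np_rows, "NP",
                       ifelse(lib$signature %in% np_sigs, "NPL", "PNP"))
  dec <- data.frame(
    source_id = sprintf("dec%02d", seq_len(n_decoy)),
    smiles = decoys$smiles[seq_len(n_decoy)],
    signature = NA_character_, frag_a = NA_integer_, frag_b = NA_integer_,
    true_ctype = NA_character_, variant = NA_integer_,
    true_status = "NonPNP", stringsAsFactors = FALSE)
  out <- rbind(lib, dec)
  rownames(out) <- NULL
  np_library <- data.frame(source_id = paste0("np_", out$source_id[np_rows]),
                           smiles = out$smiles[np_rows],
                           stringsAsFactors = FALSE)
  list(library = out, np_library = np_library, catalog = catalog)
}

#' Generate scaffold groups for subset-selection tests
#'
#' Builds a set of distinct Murcko scaffolds of exactly 17 heavy atoms (two
#' six-membered rings joined by a five-atom linker, enumerated over ring
#' and linker chemistries) and, for each scaffold, a group of member
#' compounds carrying alkyl side chains of increasing length. The result
#' mimics a PNP set ready for scaffold-based screening-subset selection.
#'
#' @param n_groups Number of scaffold groups.
#' @param members_per_group Compounds per group (side-chain variants).
#' @param seed Unused (the construction is deterministic); kept for
#'   interface symmetry.
#' @return A molecule table with `source_id`, `smiles_std`, `inchikey`,
#'   `status = "PNP"` and a `scaffold_ref` column naming the group.
#' @export
make_scaffold_groups <- function(n_groups = 300L, members_per_group = 4L,
                                 seed = 0L) {
  rings6 <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1cnncc1",
              "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1COCCN1")
  # five-atom linkers: C backbone with non-adjacent N/O substitutions at
  # interior positions, attachment carbons at both ends
  pat_sets <- list(c(3L), c(2L), c(4L), c(2L, 4L))
  linkers <- list(rep("C", 5L))
  for (pos in pat_sets) {
    grids <- do.call(expand.grid, c(rep(list(c("N", "O")), length(pos)),
                                    stringsAsFactors = FALSE))
    for (gi in seq_len(nrow(grids))) {
      lk <- rep("C", 5L)
      lk[pos] <- unlist(grids[gi, ])
      linkers[[length(linkers) + 1L]] <- lk
    }
  }
  scaff_raw <- character(0)
  for (i in seq_along(rings6)) {
    for (j in i:length(rings6)) {
      for (lk in linkers) {
        molA <- mol_from_smiles(rings6[i])
        molB <- mol_from_smiles(rings6[j])
        a <- .fg_attach_atom(molA); b <- .fg_attach_atom(molB)
        cmb <- .fg_combine(.fg_raw(molA), molB)
        raw <- cmb$raw
        prev <- a
        for (el in lk) {
          raw <- .fg_add_atom(raw, el)
          raw <- .fg_add_bond(raw, prev, length(raw$elem))
          prev <- length(raw$elem)
        }
        raw <- .fg_add_bond(raw, prev, cmb$b_map[b])
        scaff_raw <- c(scaff_raw, mol_to_smiles(.fg_finalize(raw)))
        if (length(scaff_raw) >= 2L * n_groups) break
      }
      if (length(scaff_raw) >= 2L * n_groups) break
    }
    if (length(scaff_raw) >= 2L * n_groups) break
  }
  scaff <- unique(ob_canonical_smiles(scaff_raw, strip_stereo = TRUE))
  scaff <- scaff[!is.na(scaff)]
  if (length(scaff) < n_groups) {
    stop("could only construct ", length(scaff), " distinct scaffolds")
  }
  scaff <- scaff[seq_len(n_groups)]
  member_raw <- character(0); group_ref <- character(0)
  for (g in seq_along(scaff)) {
    mol <- mol_from_smiles(scaff[g])
    a <- .fg_attach_atom(mol)
    for (m in seq_len(members_per_group)) {
      raw <- .fg_raw(mol)
      prev <- a
      for (k in seq_len(m)) {
        raw <- .fg_add_atom(raw, "C")
        raw <- .fg_add_bond(raw, prev, length(raw$elem))
        prev <- length(raw$elem)
      }
      member_raw <- c(member_raw, mol_to_smiles(.fg_finalize(raw)))
      group_ref <- c(group_ref, sprintf("scaffold%03d", g))
    }
  }
  smi <- ob_canonical_smiles(member_raw, strip_stereo = TRUE)
  keys <- ob_inchikey(smi)
  data.frame(source_id = sprintf("cpa%05d", seq_along(smi)),
             smiles_std = smi, inchikey = keys, status = "PNP",
             scaffold_ref = group_ref, stringsAsFactors = FALSE)
}

#' Generate synthetic morphological profiles with planted clusters
#'
#' Creates cluster subprofiles on disjoint feature subsets, active member
#' profiles correlating strongly (about 0.99) with their cluster's
#' reference values, and "novel activity" profiles whose signal lives on a
#' reserved feature block orthogonal to every cluster subset. All generated
#' actives have induction of at least 5 percent by construction.
#'
#' @param n_active Number of cluster-member profiles.
#' @param n_clusters Number of clusters (<= 13).
#' @param n_features Profile length (default 579).
#' @param n_novel Number of novel-activity profiles.
#' @param seed Integer seed.
#' @param subset_size Features per cluster subset.
#' @return A list: `profiles` (as from [read_profiles()]), `subprofiles`,
#'   `truth` (data.frame `id`, `cluster`; novel profiles have cluster
#'   `"novel"`).
#' @export
make_profiles <- function(n_active = 50L, n_clusters = 3L, n_features = 579L,
                          n_novel = 5L, seed = 1L, subset_size = 40L) {
  stopifnot(n_clusters >= 1L, n_clusters <= 13L,
            (n_clusters + 1L) * subset_size <= n_features)
  cluster_names <- sprintf("cluster_%02d", seq_len(n_clusters))
  .fg_with_seed(seed, {
    subsets <- lapply(seq_len(n_clusters), function(k)
      ((k - 1L) * subset_size + 1L):(k * subset_size))
    novel_subset <- (n_clusters * subset_size + 1L):((n_clusters + 1L) * subset_size)
    patterns <- lapply(seq_len(n_clusters), function(k)
      stats::runif(subset_size, 4, 6) * sample(c(-1, 1), subset_size, replace = TRUE))
    subprofiles <- lapply(seq_len(n_clusters), function(k)
      list(cluster_name = cluster_names[k], feature_subset = subsets[[k]],
           values = patterns[[k]]))
    n_total <- n_active + n_novel
    member_of <- rep(seq_len(n_clusters), length.out = n_active)
    mat <- matrix(stats::rnorm(n_total * n_features, sd = 0.5),
                  nrow = n_total, ncol = n_features)
    for (i in seq_len(n_active)) {
      k <- member_of[i]
      mat[i, subsets[[k]]] <- patterns[[k]] + stats::rnorm(subset_size, sd = 0.5)
    }
    novel_pattern <- stats::runif(subset_size, 4, 6) *
      sample(c(-1, 1), subset_size, replace = TRUE)
    for (i in seq_len(n_novel)) {
      mat[n_active + i, novel_subset] <- novel_pattern +
        stats::rnorm(subset_size, sd = 0.5)
    }
    ids <- c(sprintf("act%03d", seq_len(n_active)),
             sprintf("nov%03d", seq_len(n_novel)))
    rownames(mat) <- ids
    colnames(mat) <- sprintf("feature_%03d", seq_len(n_features))
    list(profiles = list(meta = data.frame(id = ids, concentration = 10,
                                           stringsAsFactors = FALSE),
                         mat = mat, features = colnames(mat)),
         subprofiles = subprofiles,
         truth = data.frame(id = ids,
                            cluster = c(cluster_names[member_of],
                                        rep("novel", n_novel)),
                            stringsAsFactors = FALSE))
  })
}
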