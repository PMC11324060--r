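# Fragment catalog construction: Murcko scaffolding of an input natural
# product fragment set, standardization, racemic-InChIKey deduplication and
# benzene exclusion. The catalog is the search dictionary for all fragment
# matching downstream.

# Murcko scaffold on the graph level: iteratively prune acyclic terminal
# atoms, keeping ring systems and the linkers between them, then restore
# atoms attached to the scaffold by a double or triple bond (exocyclic
# carbonyls and the like).
murcko_scaffold_mol <- function(mol) {
  if (mol$n_rings == 0L) return(NULL)
  keep <- seq_len(mol$n_atoms)
  repeat {
    sub <- fg_subgraph(mol, keep)
    drop_local <- which(!sub$ring_atom & sub$degree <= 1L & sub$n_atoms > 1L)
    if (length(drop_local) == 0L || sub$n_atoms == length(drop_local)) break
    keep <- keep[-drop_local]
  }
  # restore multiply-bonded substituents of scaffold atoms
  bonds <- mol$bonds
  extra <- integer(0)
  sel <- bonds$order %in% c(2L, 3L)
  for (k in which(sel)) {
    a <- bonds$a[k]; b <- bonds$b[k]
    if (a %in% keep && !(b %in% keep)) extra <- c(extra, b)
    if (b %in% keep && !(a %in% keep)) extra <- c(extra, a)
  }
  fg_subgraph(mol, c(keep, extra))
}

#' Murcko scaffold of a structure
#'
#' Returns the ring systems of a molecule plus the linkers connecting them,
#' with all side chains removed; substituents double- or triple-bonded to
#' the scaffold (e.g. exocyclic carbonyl oxygens) are retained. Acyclic
#' molecules have no scaffold and yield `NA`.
#'
#' @param smiles Character vector of SMILES in aromatic (canonical) form.
#' @return Character vector of canonical scaffold SMILES (`NA` for acyclic
#'   input).
#' @examples
#' \dontrun{
#' murcko_scaffold("Cc1ccccc1")   # toluene -> benzene
#' murcko_scaffold("CCC")         # acyclic -> NA
#' }
#' @export
murcko_scaffold <- function(smiles) {
  raw <- vapply(smiles, function(s) {
    mol <- tryCatch(mol_from_smiles(s), error = function(e) NULL)
    if (is.null(mol)) return(NA_character_)
    sc <- murcko_scaffold_mol(mol)
    if (is.null(sc)) NA_character_ else mol_to_smiles(sc)
  }, character(1), USE.NAMES = FALSE)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(raw)
  if (any(ok)) out[ok] <- ob_canonical_smiles(raw[ok], strip_stereo = TRUE)
  out
}

#' Build the natural-product fragment catalog
#'
#' For every input fragment: take its Murcko scaffold, standardize (racemic
#' canonical form, neutralization), then deduplicate the set by racemic
#' InChIKey and exclude benzene (detected by InChIKey equality after
#' standardization, not by SMILES string). Fragment identifiers are assigned
#' in first-seen input order, so the catalog is stable across runs for the
#' same input.
#'
#' @param fragment_smiles Character vector of fragment SMILES.
#' @return A data.frame (`fg_catalog`) with columns `frag_id`, `smiles`,
#'   `inchikey`, `num_heavy_atoms`. Acyclic or unparseable inputs are
#'   skipped with a message; if nothing remains the call fails.
#' @export
build_catalog <- function(fragment_smiles) {
  stopifnot(length(fragment_smiles) > 0L)
  canon <- ob_canonical_smiles(fragment_smiles, strip_stereo = TRUE,
                               neutralize = TRUE)
  scaff <- rep(NA_character_, length(canon))
  ok <- !is.na(canon)
  scaff[ok] <- murcko_scaffold(canon[ok])
  n_acyclic <- sum(ok & is.na(scaff))
  if (n_acyclic > 0L) message(n_acyclic, " acyclic fragment(s) skipped")
  std <- rep(NA_character_, length(scaff))
  keys <- rep(NA_character_, length(scaff))
  ok <- !is.na(scaff)
  if (any(ok)) {
    res <- standardize_structures(scaff[ok], deglyco = FALSE, neutralize = TRUE)
    std[ok] <- res$smiles_std
    keys[ok] <- res$inchikey
  }
  keep <- !is.na(std) & !is.na(keys)
  if (!any(keep)) stop("no usable (cyclic) fragments in input")
  std <- std[keep]; keys <- keys[keep]
  first <- !duplicated(keys)
  std <- std[first]; keys <- keys[first]
  benzene_key <- ob_inchikey("c1ccccc1")
  benz <- keys == benzene_key
  std <- std[!benz]; keys <- keys[!benz]
  if (length(std) == 0L) stop("catalog is empty after benzene exclusion")
  nha <- vapply(std, function(s) mol_from_smiles(s)$n_atoms, integer(1),
                USE.NAMES = FALSE)
  structure(data.frame(frag_id = seq_along(std), smiles = std,
                       inchikey = keys, num_heavy_atoms = nha,
                       stringsAsFactors = FALSE),
            class = c("fg_catalog", "data.frame"))
}

#' Read / write a fragment catalog
#'
#' @param path TSV file with columns `frag_id`, `smiles`, `inchikey`,
#'   `num_heavy_atoms`.
#' @return `read_catalog()` returns the catalog data.frame.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frag_id", "smiles", "inchikey", "num_heavy_atoms") %in% names(tab)))
  structure(tab, class = c("fg_catalog", "data.frame"))
}

#' @rdname read_catalog
#' @param catalog A catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
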