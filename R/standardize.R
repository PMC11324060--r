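# Structure standardization: reading compound tables, canonical racemic
# SMILES, salt stripping, neutralization, deglycosylation, structural
# filters, InChIKey deduplication and the chunked/timeout-guarded map.
#
# A "molecule table" is a data.frame with one row per library entry:
#   source_id, smiles_input, smiles_std, inchikey, mw, num_rings,
#   num_heavy_atoms, passed_filters, status, failure_reason

#' Default pipeline configuration
#'
#' @param chunk_size Number of records processed per chunk. Chunking is an
#'   implementation detail only: outputs are identical for every chunk size.
#' @param timeout_s Per-molecule wall-clock budget (seconds) for the fragment
#'   analysis stage; molecules exceeding it are marked failed (NonPNP with a
#'   failure reason) instead of aborting the run.
#' @param random_seed Seed for all randomized steps.
#' @param connection_cutoff Maximum linker length in bonds for two fragments
#'   to count as connected (see [classify_pair()]).
#' @param fcg_compare_level `"edge"` (default) compares molecules to the NP
#'   reference one pairwise fragment combination at a time; `"graph"`
#'   compares whole fragment-combination-graph signatures.
#' @param deglycosylate Remove terminal sugar rings during standardization.
#' @param neutralize Neutralize +1/-1 charges during standardization.
#' @return A list of class `fg_config`.
#' @export
fg_config <- function(chunk_size = 100L, timeout_s = 50, random_seed = 1L,
                      connection_cutoff = 3L,
                      fcg_compare_level = c("edge", "graph"),
                      deglycosylate = TRUE, neutralize = TRUE) {
  fcg_compare_level <- match.arg(fcg_compare_level)
  stopifnot(timeout_s > 0, chunk_size >= 1L, connection_cutoff >= 1L)
  structure(list(chunk_size = as.integer(chunk_size), timeout_s = timeout_s,
                 random_seed = as.integer(random_seed),
                 connection_cutoff = as.integer(connection_cutoff),
                 fcg_compare_level = fcg_compare_level,
                 deglycosylate = isTRUE(deglycosylate),
                 neutralize = isTRUE(neutralize)),
            class = "fg_config")
}

.fg_empty_molecule_table <- function(n = 0L) {
  data.frame(source_id = character(n), smiles_input = character(n),
             smiles_std = rep(NA_character_, n), inchikey = rep(NA_character_, n),
             mw = rep(NA_real_, n), num_rings = rep(NA_integer_, n),
             num_heavy_atoms = rep(NA_integer_, n),
             passed_filters = rep(NA, n), status = rep(NA_character_, n),
             failure_reason = rep(NA_character_, n), stringsAsFactors = FALSE)
}

#' Read a compound table from SMILES-TSV or SDF
#'
#' SMILES-TSV files must be tab-separated with a header containing at least
#' the columns `id` and `smiles`. SDF reading uses ChemmineR. Entries whose
#' SMILES cannot be parsed at all are dropped with a message; their count is
#' available as `attr(x, "n_rejected")`.
#'
#' @param path Input file.
#' @param format `"smiles-tsv"` or `"sdf"`.
#' @return A molecule table with `source_id` and `smiles_input` populated.
#' @export
read_molecule_table <- function(path, format = c("smiles-tsv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "smiles-tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c("id", "smiles") %in% names(tab))) {
      stop("SMILES-TSV requires 'id' and 'smiles' columns; found: ",
           paste(names(tab), collapse = ", "))
    }
    ids <- as.character(tab$id); smi <- as.character(tab$smiles)
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE)) {
      stop("reading SDF requires the ChemmineR package")
    }
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    sdf <- sdf[valid]
    smi_obj <- ChemmineR::sdf2smiles(sdf)
    smi <- as.character(smi_obj)
    ids <- ChemmineR::sdfid(sdf)
    if (any(!valid)) message(sum(!valid), " invalid SDF record(s) dropped")
  }
  keep <- !is.na(smi) & nzchar(trimws(smi))
  parse_ok <- vapply(smi, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    !inherits(tryCatch(mol_from_smiles(s), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
  keep <- keep & parse_ok
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    message(n_rejected, " unparseable record(s) rejected: ",
            paste(utils::head(ids[!keep], 5L), collapse = ", "),
            if (n_rejected > 5L) ", ..." else "")
  }
  if (!any(keep)) stop("no parseable records in ", path)
  out <- .fg_empty_molecule_table(sum(keep))
  out$source_id <- ids[keep]
  out$smiles_input <- trimws(smi[keep])
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a molecule table to TSV
#'
#' @param records A molecule table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# pick the largest organic component (most heavy atoms; organic = contains
# carbon). Ties are broken by Open Babel canonical SMILES string order.
.fg_largest_organic <- function(mol) {
  comps <- fg_components(mol)
  if (length(comps) == 1L) return(mol)
  has_c <- vapply(comps, function(a) any(mol$elem[a] == "C"), logical(1))
  cand <- if (any(has_c)) comps[has_c] else comps
  sizes <- lengths(cand)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    smis <- vapply(cand[best], function(a) mol_to_smiles(fg_subgraph(mol, a)),
                   character(1))
    canon <- ob_canonical_smiles(smis, strip_stereo = TRUE)
    canon[is.na(canon)] <- smis[is.na(canon)]
    best <- best[order(canon)][1]
  } else best <- best[1]
  fg_subgraph(mol, cand[[best]])
}

#' Standardize structures to canonical racemic form
#'
#' Vectorized standardization: Open Babel parsing and canonicalization with
#' stereo removal (racemization) and optional charge neutralization, largest
#' organic component selection (salt/solvent stripping), optional
#' deglycosylation, re-canonicalization, and racemic InChIKey generation.
#'
#' @param smiles Character vector of input SMILES.
#' @param deglyco Remove terminal sugar rings (see [deglycosylate()]).
#' @param neutralize Neutralize +1/-1 charges.
#' @return A data.frame with columns `smiles_std`, `inchikey`,
#'   `failure_reason` (NA when standardization succeeded).
#' @export
standardize_structures <- function(smiles, deglyco = TRUE, neutralize = TRUE) {
  n <- length(smiles)
  out <- data.frame(smiles_std = rep(NA_character_, n),
                    inchikey = rep(NA_character_, n),
                    failure_reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  canon <- ob_canonical_smiles(smiles, strip_stereo = TRUE, neutralize = neutralize)
  out$failure_reason[is.na(canon)] <- "unparseable structure"
  work <- which(!is.na(canon))
  post <- rep(NA_character_, n)
  for (i in work) {
    res <- tryCatch({
      mol <- mol_from_smiles(canon[i])
      mol <- .fg_largest_organic(mol)
      if (deglyco) mol <- deglycosylate_mol(mol)
      mol_to_smiles(mol)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$failure_reason[i] <- paste0("standardization failed: ",
                                      conditionMessage(res))
    } else post[i] <- res
  }
  work <- which(!is.na(post))
  if (length(work) > 0L) {
    final <- ob_canonical_smiles(post[work], strip_stereo = TRUE)
    keys <- ob_inchikey(final)
    out$smiles_std[work] <- final
    out$inchikey[work] <- keys
    bad <- work[is.na(final) | is.na(keys)]
    out$failure_reason[bad] <- "canonicalization failed"
    out$smiles_std[bad] <- NA_character_
    out$inchikey[bad] <- NA_character_
  }
  out
}

#' Standardize a single structure
#'
#' @param smiles_input A single SMILES string.
#' @param deglyco,neutralize See [standardize_structures()].
#' @return A list with `smiles_std` and `inchikey`.
#' @export
standardize_structure <- function(smiles_input, deglyco = TRUE, neutralize = TRUE) {
  res <- standardize_structures(smiles_input, deglyco = deglyco,
                                neutralize = neutralize)
  if (!is.na(res$failure_reason[1])) {
    stop("standardization of '", smiles_input, "' failed: ",
         res$failure_reason[1], call. = FALSE)
  }
  list(smiles_std = res$smiles_std[1], inchikey = res$inchikey[1])
}

#' Structural filters
#'
#' A standardized molecule passes when it has at least one ring and a
#' molecular weight below 1000 g/mol.
#'
#' @param num_rings Ring count (cyclomatic number) of the standardized
#'   structure.
#' @param mw Molecular weight in g/mol.
#' @return Logical vector.
#' @export
apply_filters <- function(num_rings, mw) {
  !is.na(num_rings) & !is.na(mw) & num_rings > 0L & mw < 1000
}

#' Deduplicate a molecule table by InChIKey
#'
#' Keeps the first occurrence of every InChIKey (racemic identity), in input
#' order. Records without an InChIKey (failed standardization) are kept.
#' The number of removed duplicates is stored in `attr(x, "n_duplicates")`.
#'
#' @param records A molecule table with `inchikey` populated.
#' @return The deduplicated table.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) {
    attr(records, "n_duplicates") <- 0L
    return(records)
  }
  dup <- duplicated(records$inchikey) & !is.na(records$inchikey)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Apply a per-record operation in chunks with a per-record timeout
#'
#' The operation must be pure per record: results are identical,
#' element-for-element, to a single-chunk run for every chunk size. A record
#' whose computation exceeds the configured wall-clock budget yields an
#' object of class `fg_timeout` instead of a result; the run continues.
#'
#' @param records A list (or data.frame, processed row-wise).
#' @param op Function of one record.
#' @param config An [fg_config()].
#' @return A list of results, one per record; timed-out records carry class
#'   `fg_timeout`, records whose operation raised an error carry class
#'   `fg_failure` (with the message in `$message`).
#' @export
chunked_map <- function(records, op, config = fg_config()) {
  items <- if (is.data.frame(records)) {
    lapply(seq_len(nrow(records)), function(i) records[i, , drop = FALSE])
  } else as.list(records)
  n <- length(items)
  if (n == 0L) return(list())
  results <- vector("list", n)
  starts <- seq(1L, n, by = config$chunk_size)
  for (s in starts) {
    idx <- s:min(s + config$chunk_size - 1L, n)
    for (i in idx) {
      results[[i]] <- .fg_with_timeout(function() op(items[[i]]), config$timeout_s)
    }
  }
  results
}

.fg_with_timeout <- function(thunk, timeout_s) {
  res <- tryCatch({
    setTimeLimit(elapsed = timeout_s, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    thunk()
  }, error = function(e) {
    setTimeLimit(elapsed = Inf)
    msg <- conditionMessage(e)
    if (grepl("time limit", msg, fixed = TRUE) ||
        grepl("elapsed", msg, fixed = TRUE)) {
      structure(list(message = msg), class = c("fg_timeout", "fg_failure"))
    } else {
      structure(list(message = msg), class = "fg_failure")
    }
  })
  res
}

#' Standardize a compound library
#'
#' Runs the full preprocessing stage on a molecule table: standardization
#' (racemization, salt stripping, neutralization, optional deglycosylation),
#' descriptor computation, structural filters, and InChIKey deduplication.
#' Processing is batched in chunks of `config$chunk_size`; outputs do not
#' depend on the chunk size.
#'
#' @param records A molecule table from [read_molecule_table()].
#' @param config An [fg_config()].
#' @param dedup Deduplicate by InChIKey after standardization.
#' @return The completed molecule table; `attr(,"n_duplicates")` reports how
#'   many duplicate records were removed.
#' @export
standardize_library <- function(records, config = fg_config(), dedup = TRUE) {
  n <- nrow(records)
  if (n == 0L) return(records)
  starts <- seq(1L, n, by = config$chunk_size)
  for (s in starts) {
    idx <- s:min(s + config$chunk_size - 1L, n)
    std <- standardize_structures(records$smiles_input[idx],
                                  deglyco = config$deglycosylate,
                                  neutralize = config$neutralize)
    records$smiles_std[idx] <- std$smiles_std
    records$inchikey[idx] <- std$inchikey
    records$failure_reason[idx] <- std$failure_reason
  }
  ok <- !is.na(records$smiles_std)
  for (i in which(ok)) {
    mol <- mol_from_smiles(records$smiles_std[i])
    records$mw[i] <- mol$mw
    records$num_rings[i] <- mol$n_rings
    records$num_heavy_atoms[i] <- mol$n_atoms
  }
  records$passed_filters <- apply_filters(records$num_rings, records$mw) & ok
  records$status[!ok] <- "NonPNP"
  if (dedup) records <- deduplicate(records)
  records
}
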