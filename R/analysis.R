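# Library-level aggregation: status distribution, connection/fusion type
# statistics, fragment and fragment-combination frequencies, scaffold-based
# selection of a cell-painting screening subset, and PAINS triage.

# run expr with a locally seeded RNG, restoring the caller's RNG state
.fg_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Summarize a classified library
#'
#' Computes the status distribution over deduplicated molecules and, over
#' PNP molecules only, the distribution of combination types (as percent of
#' all typed edges and as a ratio scaled so that cm = 100), the most
#' frequent fragments and the most frequent pairwise fragment combinations
#' (each as percent of PNP molecules containing them).
#'
#' @param records Molecule table with `status` assigned.
#' @param fcg_table Output of [classify_library()] for `records`.
#' @return A list of class `fg_library_summary`: `status_counts`,
#'   `ctype_percent`, `ctype_ratio`, `top_fragments`, `top_combinations`,
#'   `n_molecules`.
#' @export
summarize_library <- function(records, fcg_table) {
  if (nrow(records) == 0L) {
    warning("empty library; returning empty summary")
    return(structure(list(status_counts = integer(0),
                          ctype_percent = numeric(0), ctype_ratio = numeric(0),
                          top_fragments = data.frame(), top_combinations = data.frame(),
                          n_molecules = 0L), class = "fg_library_summary"))
  }
  status_counts <- table(factor(records$status,
                                levels = c("PNP", "NPL", "NP", "NonPNP")))
  pnp_ids <- records$source_id[records$status %in% "PNP"]
  sub <- fcg_table[fcg_table$source_id %in% pnp_ids, , drop = FALSE]
  edge_strings <- unlist(strsplit(sub$edges, ";", fixed = TRUE), use.names = FALSE)
  ctypes <- vapply(strsplit(edge_strings, ":", fixed = TRUE), `[`, character(1), 3L)
  ctype_counts <- sort(table(ctypes), decreasing = TRUE)
  total <- sum(ctype_counts)
  ctype_percent <- if (total > 0L) 100 * as.numeric(ctype_counts) / total else numeric(0)
  names(ctype_percent) <- names(ctype_counts)
  ctype_ratio <- numeric(0)
  if (total > 0L && "cm" %in% names(ctype_counts)) {
    ctype_ratio <- 100 * as.numeric(ctype_counts) / as.numeric(ctype_counts[["cm"]])
    names(ctype_ratio) <- names(ctype_counts)
  }
  # per-molecule presence of fragments and of edge strings
  frag_tab <- combo_tab <- data.frame()
  if (nrow(sub) > 0L) {
    per_mol <- split(sub$edges, sub$source_id)
    frags_by_mol <- lapply(per_mol, function(e) {
      es <- unlist(strsplit(e, ";", fixed = TRUE), use.names = FALSE)
      parts <- strsplit(es, ":", fixed = TRUE)
      unique(unlist(lapply(parts, function(p) p[1:2])))
    })
    combos_by_mol <- lapply(per_mol, function(e)
      unique(unlist(strsplit(e, ";", fixed = TRUE), use.names = FALSE)))
    n_pnp <- length(per_mol)
    ft <- sort(table(unlist(frags_by_mol)), decreasing = TRUE)
    frag_tab <- data.frame(frag_id = as.integer(names(ft)),
                           percent = 100 * as.numeric(ft) / n_pnp)
    ct <- sort(table(unlist(combos_by_mol)), decreasing = TRUE)
    combo_tab <- data.frame(combination = names(ct),
                            percent = 100 * as.numeric(ct) / n_pnp)
  }
  structure(list(status_counts = status_counts,
                 ctype_percent = ctype_percent, ctype_ratio = ctype_ratio,
                 top_fragments = frag_tab, top_combinations = combo_tab,
                 n_molecules = nrow(records)),
            class = "fg_library_summary")
}

#' @export
print.fg_library_summary <- function(x, ...) {
  cat("Library summary over", x$n_molecules, "molecules\n")
  print(x$status_counts)
  if (length(x$ctype_percent)) {
    cat("Combination types (% of typed edges, PNP compounds only):\n")
    print(round(x$ctype_percent, 1))
  }
  invisible(x)
}

#' Select a scaffold-based screening subset
#'
#' Groups PNP compounds by the racemic InChIKey of their Murcko scaffold,
#' keeps groups whose scaffold has exactly `scaffold_heavy_atoms` heavy
#' atoms and at least `min_group` members, then draws `n_scaffolds` groups
#' and `per_scaffold` members per group, both uniformly without replacement
#' under a single seeded generator. Groups are pre-sorted by scaffold
#' InChIKey (and members by `source_id`), so a given seed reproduces the
#' identical selection on any platform.
#'
#' @param pnp_records Molecule table (typically the PNP subset).
#' @param scaffold_heavy_atoms Required scaffold size (heavy atoms).
#' @param min_group Minimum group size.
#' @param n_scaffolds Number of scaffold groups to draw.
#' @param per_scaffold Members drawn per group.
#' @param seed Integer seed.
#' @return The selected records with `scaffold_smiles` and
#'   `scaffold_inchikey` columns added; `nrow = n_scaffolds * per_scaffold`.
#' @export
select_cpa_subset <- function(pnp_records, scaffold_heavy_atoms = 17L,
                              min_group = 4L, n_scaffolds = 250L,
                              per_scaffold = 4L, seed = 1L) {
  stopifnot(nrow(pnp_records) > 0L)
  scaff <- murcko_scaffold(pnp_records$smiles_std)
  keys <- rep(NA_character_, length(scaff))
  ok <- !is.na(scaff)
  keys[ok] <- ob_inchikey(scaff[ok])
  nha <- rep(NA_integer_, length(scaff))
  nha[ok] <- vapply(scaff[ok], function(s) mol_from_smiles(s)$n_atoms,
                    integer(1), USE.NAMES = FALSE)
  recs <- pnp_records
  recs$scaffold_smiles <- scaff
  recs$scaffold_inchikey <- keys
  recs <- recs[ok & nha == scaffold_heavy_atoms, , drop = FALSE]
  groups <- split(seq_len(nrow(recs)), recs$scaffold_inchikey)
  groups <- groups[lengths(groups) >= min_group]
  if (length(groups) < n_scaffolds) {
    stop("only ", length(groups), " qualifying scaffold groups (need ",
         n_scaffolds, ")")
  }
  groups <- groups[order(names(groups))]
  sel <- .fg_with_seed(seed, {
    picked <- sample(names(groups), n_scaffolds)
    unlist(lapply(picked, function(key) {
      idx <- groups[[key]]
      idx <- idx[order(recs$source_id[idx])]
      sample(idx, per_scaffold)
    }), use.names = FALSE)
  })
  out <- recs[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove PAINS matches from a library
#'
#' Screens standardized structures against a curated set of published PAINS
#' (pan-assay interference) substructure patterns shipped with the package
#' and removes every record matching any of them.
#'
#' @param records Molecule table with `smiles_std`.
#' @param patterns Optional data.frame with columns `name`, `smarts`;
#'   defaults to the shipped catalog.
#' @return Records without PAINS matches; `attr(,"removed")` is a
#'   data.frame of `source_id` and the matching `pattern`.
#' @export
pains_filter <- function(records, patterns = NULL) {
  if (is.null(patterns)) {
    path <- system.file("extdata", "pains_smarts.tsv", package = "fraggraph")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "pains_smarts.tsv")
    patterns <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0L) {
    attr(records, "removed") <- data.frame(source_id = character(0),
                                           pattern = character(0))
    return(records)
  }
  hit_pattern <- rep(NA_character_, nrow(records))
  for (k in seq_len(nrow(patterns))) {
    m <- ob_smarts_match(records$smiles_std, patterns$smarts[k])
    new_hit <- m & is.na(hit_pattern)
    hit_pattern[new_hit] <- patterns$name[k]
  }
  removed <- data.frame(source_id = records$source_id[!is.na(hit_pattern)],
                        pattern = hit_pattern[!is.na(hit_pattern)],
                        stringsAsFactors = FALSE)
  if (nrow(removed) > 0L) {
    message(nrow(removed), " PAINS match(es) removed")
  }
  out <- records[is.na(hit_pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
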