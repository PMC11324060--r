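# Shared fixtures, memoized: the expensive generators (toy catalog,
# composition enumeration, scaffold groups) are built once per test run.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_toy_catalog <- function() fx_memo("toy_catalog", function() make_toy_catalog())

fx_compositions <- function() fx_memo("compositions", function()
  enumerate_compositions(fx_toy_catalog()))

fx_scaffold_groups <- function() fx_memo("scaffold_groups", function()
  make_scaffold_groups(n_groups = 300L, members_per_group = 5L))

fx_three_frag_catalog <- function() fx_memo("three_frag", function()
  build_catalog(c("c1ccncc1", "C1CCNCC1", "C1CCCC1")))

# write a synthetic library to TSV files in a fresh temp dir; returns paths
fx_write_library <- function(syn, dir = tempfile("synlib")) {
  dir.create(dir, recursive = TRUE)
  paths <- list(library = file.path(dir, "library.tsv"),
                np_library = file.path(dir, "np_library.tsv"),
                fragments = file.path(dir, "fragments.tsv"),
                dir = dir)
  utils::write.table(data.frame(id = syn$library$source_id,
                                smiles = syn$library$smiles),
                     paths$library, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = syn$np_library$source_id,
                                smiles = syn$np_library$smiles),
                     paths$np_library, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = paste0("f", syn$catalog$frag_id),
                                smiles = syn$catalog$smiles),
                     paths$fragments, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# three-fragment universe (pyridine = 1, piperidine = 2, cyclopentane = 3)
# with a constructed NP library, used by the status truth-table checks
fx_universe <- function() fx_memo("universe", function() {
  catalog <- fx_three_frag_catalog()
  lib <- data.frame(
    source_id = c("m_pp", "m_pc", "m_both", "m_np1", "m_np2", "m_novel",
                  "m_benz", "m_single", "m_acyclic"),
    smiles = c("C(c1ccncc1)C1CCNCC1",                # 1:2:cm
               "C(c1ccncc1)C1CCCC1",                 # 1:3:cm
               "c1cc(CC2CCNCC2)ncc1CC2CCCC2",        # 1:2:cm and 1:3:cm
               "CC(c1ccncc1)C1CCNCC1",               # NP, 1:2:cm
               "CC(c1ccncc1)C1CCCC1",                # NP, 1:3:cm
               "C(C1CCCC1)C1CCNCC1",                 # 2:3:cm, unseen in NPs
               "c1ccccc1", "Cc1ccncc1", "CCCC"),
    stringsAsFactors = FALSE)
  recs <- fraggraph:::.fg_empty_molecule_table(nrow(lib))
  recs$source_id <- lib$source_id
  recs$smiles_input <- lib$smiles
  cfg <- fg_config()
  recs <- standardize_library(recs, cfg)
  np <- recs[recs$source_id %in% c("m_np1", "m_np2"), , drop = FALSE]
  fcg <- classify_library(recs, catalog, cfg)
  np_fcg <- fcg[fcg$source_id %in% np$source_id, , drop = FALSE]
  list(catalog = catalog, recs = recs, np = np, fcg = fcg, np_fcg = np_fcg,
       cfg = cfg)
})

fx_synlib_run <- function() fx_memo("synlib_run", function() {
  syn <- make_synthetic_library(n = 120L, np_fraction = 0.2, seed = 7L)
  paths <- fx_write_library(syn)
  out <- run_pipeline(list(library = paths$library,
                           np_library = paths$np_library,
                           fragments = paths$fragments,
                           out_dir = file.path(paths$dir, "out")))
  list(syn = syn, paths = paths, out = out)
})
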