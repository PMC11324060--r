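# Synthetic fixture generators: toy catalog, composer, ground-truth
# library, scaffold groups.

test_that("the toy catalog is stable, benzene-free and large enough", {
  cat1 <- fx_toy_catalog()
  cat2 <- make_toy_catalog()
  expect_identical(cat1$smiles, cat2$smiles)
  expect_gte(nrow(cat1), 8L)
  expect_false(ob_inchikey("c1ccccc1") %in% cat1$inchikey)
})

test_that("unrealizable compositions produce a loud skip signal", {
  # a spiro atom cannot sit on an aromatic ring
  res <- compose_molecule("c1cccnc1", "c1cccnc1", "fs")
  expect_true(is_skip(res))
  expect_match(res$reason, "spiro")
  # aromatic and saturated rings cannot share an edge fusion bond
  res2 <- compose_molecule("c1cccnc1", "C1CCCC1", "fe")
  expect_true(is_skip(res2))
})

test_that("the composer covers all five requested combination types", {
  comps <- fx_compositions()
  expect_gte(nrow(comps), 100L)
  expect_setequal(unique(comps$ctype), c("cm", "fe", "fs", "fb", "cbe"))
})

test_that("every composed molecule round-trips to its intended type", {
  comps <- fx_compositions()
  catalog <- fx_toy_catalog()
  idx <- fg_catalog_index(catalog)
  cfg <- fg_config()
  sigs <- vapply(seq_len(nrow(comps)), function(k) {
    r <- molecule_fcgs(comps$smiles[k], catalog, cfg, index = idx)
    if (length(r$fcgs) != 1L) return("<none>")
    r$fcgs[[1]]$signature
  }, character(1))
  expect_identical(sigs, comps$signature)
})

test_that("the synthetic library carries correct a-priori statuses", {
  run <- fx_synlib_run()
  m <- merge(run$out$status[, c("source_id", "status")],
             run$syn$library[, c("source_id", "true_status")],
             by = "source_id")
  expect_equal(nrow(m), nrow(run$syn$library))
  expect_identical(m$status, m$true_status)
  expect_setequal(unique(m$status), c("PNP", "NPL", "NP", "NonPNP"))
  # acyclic decoys fail the filters and end up NonPNP
  dec <- run$out$status[run$out$status$source_id == "dec04", ]
  expect_false(dec$passed_filters)
  expect_identical(dec$status, "NonPNP")
  # records copied into the NP library are NP by structural identity
  np_ids <- sub("^np_", "", run$syn$np_library$source_id)
  expect_true(all(m$status[m$source_id %in% np_ids] == "NP"))
})

test_that("scaffold groups deliver 17-heavy-atom scaffolds in groups", {
  grp <- fx_scaffold_groups()
  expect_equal(length(unique(grp$scaffold_ref)), 300L)
  expect_true(all(table(grp$scaffold_ref) == 5L))
  expect_false(any(duplicated(grp$inchikey)))
  some <- grp$smiles_std[!duplicated(grp$scaffold_ref)][1:20]
  scaff <- murcko_scaffold(some)
  ha <- vapply(scaff, function(s) mol_from_smiles(s)$n_atoms, integer(1))
  expect_true(all(ha == 17L))
})
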