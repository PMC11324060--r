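# Fragment matching and the fusion/connection taxonomy.

test_that("fragment hits cover expected matches and collapse symmetry", {
  catalog <- fx_toy_catalog()
  pyridine_id <- catalog$frag_id[catalog$inchikey == ob_inchikey("c1ccncc1")]
  # the fragment itself: one hit covering all heavy atoms
  hits <- find_fragment_hits("c1cccnc1", catalog)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$frag_id, pyridine_id)
  expect_equal(length(hits$atoms[[1]]), 6L)
  # two pyridines joined by an ethylene: occurrences 0 and 1
  hits2 <- find_fragment_hits("C(c1cccnc1)Cc1cccnc1", catalog)
  expect_equal(nrow(hits2), 2L)
  expect_equal(hits2$occurrence, c(0L, 1L))
  expect_equal(length(unique(lapply(hits2$atoms, sort))), 2L)
  # no catalog substructure
  expect_equal(nrow(find_fragment_hits("c1ccccc1", catalog)), 0L)
})

test_that("pair classification covers every taxonomy branch", {
  catalog <- fx_toy_catalog()
  idx <- fg_catalog_index(catalog)
  cfg <- fg_config()
  sig1 <- function(smi) {
    r <- molecule_fcgs(smi, catalog, cfg, index = idx)
    vapply(r$fcgs, function(f) f$signature, character(1))
  }
  cp <- catalog$frag_id[catalog$inchikey == ob_inchikey("C1CCCC1")]
  py <- catalog$frag_id[catalog$inchikey == ob_inchikey("c1ccncc1")]
  expect_equal(sig1("C1CCC2(C1)CCCC2"), sprintf("%d:%d:fs", cp, cp))
  expect_equal(sig1("C1CC2CCC1C2"), sprintf("%d:%d:fb", cp, cp))
  expect_equal(sig1("C(c1cccnc1)Cc1cccnc1"), sprintf("%d:%d:cm", py, py))
  expect_equal(sig1("c1cnccc1-c1ccncc1"), sprintf("%d:%d:cm", py, py))
  # beyond the 3-bond cutoff: no edge at all
  expect_length(sig1("c1ccncc1CCCCCCc1ccncc1"), 0L)
})

test_that("edge fusion and bipodal connection arise from composed pairs", {
  catalog <- fx_toy_catalog()
  pip <- catalog$smiles[catalog$inchikey == ob_inchikey("C1CCNCC1")]
  thio <- catalog$smiles[catalog$inchikey == ob_inchikey("c1ccsc1")]
  fe <- compose_molecule(pip, pip, "fe", frag_ids = c(2L, 2L))
  expect_false(is_skip(fe))
  hits <- find_fragment_hits(fe$smiles, catalog)
  expect_equal(nrow(hits), 2L)
  expect_equal(classify_pair(hits$atoms[[1]], hits$atoms[[2]], fe$smiles), "fe")
  cbe <- compose_molecule(thio, thio, "cbe", frag_ids = c(5L, 5L))
  expect_false(is_skip(cbe))
  hits2 <- find_fragment_hits(cbe$smiles, catalog)
  expect_equal(classify_pair(hits2$atoms[[1]], hits2$atoms[[2]], cbe$smiles),
               "cbe")
})

test_that("classification is symmetric over all composed pairs", {
  comps <- fx_compositions()
  catalog <- fx_toy_catalog()
  idx <- fg_catalog_index(catalog)
  cfg <- fg_config()
  for (k in seq_len(nrow(comps))) {
    mol <- mol_from_smiles(comps$smiles[k])
    hits <- find_fragment_hits(mol, catalog, index = idx)
    expect_equal(nrow(hits), 2L, info = comps$smiles[k])
    ab <- classify_pair(hits$atoms[[1]], hits$atoms[[2]], mol,
                        cfg$connection_cutoff)
    ba <- classify_pair(hits$atoms[[2]], hits$atoms[[1]], mol,
                        cfg$connection_cutoff)
    expect_identical(ab, ba, info = comps$smiles[k])
  }
})

test_that("containment discards the smaller hit before FCG construction", {
  catalog <- build_catalog(c("c1ccncc1", "c1ccc2ncccc2c1"))  # pyridine, quinoline
  res <- molecule_fcgs("c1ccc2ncccc2c1", catalog)
  expect_equal(nrow(res$hits), 1L)          # pyridine hit inside quinoline gone
  expect_equal(res$hits$frag_id, 2L)
  expect_length(res$fcgs, 0L)               # single hit: no FCG
})

test_that("signatures are canonical and stable under SMILES round trips", {
  edges <- data.frame(frag_a = c(7L, 9L), frag_b = c(3L, 5L),
                      ctype = c("cm", "fe"))
  expect_identical(canonical_signature(edges[1, ]), "3:7:cm")
  expect_identical(canonical_signature(edges), "3:7:cm|5:9:fe")
  catalog <- fx_toy_catalog()
  cfg <- fg_config()
  comps <- fx_compositions()
  pick <- comps[seq(1, nrow(comps), by = 17), ]
  for (k in seq_len(nrow(pick))) {
    r1 <- molecule_fcgs(pick$smiles[k], catalog, cfg)
    rt <- ob_canonical_smiles(mol_to_smiles(mol_from_smiles(pick$smiles[k])))
    r2 <- molecule_fcgs(rt, catalog, cfg)
    expect_identical(vapply(r1$fcgs, `[[`, character(1), "signature"),
                     vapply(r2$fcgs, `[[`, character(1), "signature"),
                     info = pick$smiles[k])
  }
})

test_that("FCG assembly groups connected components and skips isolated hits", {
  hits <- data.frame(frag_id = c(1L, 2L, 3L, 4L, 5L),
                     occurrence = rep(0L, 5))
  hits$atoms <- list(1:3, 4:6, 7:9, 10:12, 13:15)
  edges <- data.frame(hit_a = c(1L, 3L), hit_b = c(2L, 4L),
                      frag_a = c(1L, 3L), frag_b = c(2L, 4L),
                      ctype = c("cm", "fe"), stringsAsFactors = FALSE)
  fcgs <- build_fcgs(hits, edges)
  expect_length(fcgs, 2L)
  expect_setequal(vapply(fcgs, `[[`, character(1), "signature"),
                  c("1:2:cm", "3:4:fe"))
  expect_length(build_fcgs(hits[1, ], edges[0, ]), 0L)
})
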