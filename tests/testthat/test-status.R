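# PNP/NPL/NP/NonPNP assignment against a constructed NP reference in a
# three-fragment universe (pyridine = 1, piperidine = 2, cyclopentane = 3).

test_that("the hand-computed status table holds at edge comparison level", {
  u <- fx_universe()
  ref <- build_np_reference(u$np, u$catalog, u$cfg, fcg_table = u$np_fcg)
  expect_setequal(ref$np_signatures, c("1:2:cm", "1:3:cm"))
  out <- assign_status(u$recs, u$fcg, ref)
  got <- stats::setNames(out$status, out$source_id)
  expect_identical(got[["m_pp"]], "NPL")
  expect_identical(got[["m_pc"]], "NPL")
  expect_identical(got[["m_both"]], "NPL")   # both edges occur in NPs
  expect_identical(got[["m_np1"]], "NP")     # structural identity wins
  expect_identical(got[["m_np2"]], "NP")
  expect_identical(got[["m_novel"]], "PNP")  # 2:3:cm unseen in NPs
  expect_identical(got[["m_benz"]], "NonPNP")
  expect_identical(got[["m_single"]], "NonPNP")
  expect_identical(got[["m_acyclic"]], "NonPNP")
})

test_that("graph-level comparison flags unseen edge combinations as PNP", {
  u <- fx_universe()
  cfg_g <- fg_config(fcg_compare_level = "graph")
  ref <- build_np_reference(u$np, u$catalog, cfg_g, fcg_table = u$np_fcg)
  out <- assign_status(u$recs, u$fcg, ref)
  got <- stats::setNames(out$status, out$source_id)
  # m_both combines two NP edges into a graph never seen as a whole
  expect_identical(got[["m_both"]], "PNP")
  expect_identical(got[["m_pp"]], "NPL")
  expect_identical(got[["m_novel"]], "PNP")
  expect_identical(got[["m_np1"]], "NP")
})

test_that("a molecule with one known and one novel edge is PNP", {
  u <- fx_universe()
  ref <- structure(list(np_inchikeys = character(0),
                        np_signatures = "1:2:cm", fcg_compare_level = "edge"),
                   class = "fg_np_reference")
  expect_identical(classify_molecule("XXXXXXXXXXXXXX-XXXXXXXXXX-X",
                                     "1:2:cm|1:3:cm", ref), "PNP")
  # identity beats even a novel combination
  ref2 <- structure(list(np_inchikeys = "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                         np_signatures = character(0),
                         fcg_compare_level = "edge"),
                    class = "fg_np_reference")
  expect_identical(classify_molecule("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                                     "9:9:fe", ref2), "NP")
  expect_identical(classify_molecule("CCCCCCCCCCCCCC-DDDDDDDDDD-N",
                                     character(0), ref2), "NonPNP")
})

test_that("statuses partition the library and respond monotonically", {
  u <- fx_universe()
  ref <- build_np_reference(u$np, u$catalog, u$cfg, fcg_table = u$np_fcg)
  out <- assign_status(u$recs, u$fcg, ref)
  counts <- table(factor(out$status, levels = c("PNP", "NPL", "NP", "NonPNP")))
  expect_equal(sum(counts), nrow(out))
  # enlarging the signature set can only move PNP -> NPL
  ref_big <- ref
  ref_big$np_signatures <- sort(union(ref$np_signatures, "2:3:cm"))
  out_big <- assign_status(u$recs, u$fcg, ref_big)
  moved <- out$status != out_big$status
  expect_true(all(out$status[moved] == "PNP" & out_big$status[moved] == "NPL"))
  # adding a molecule's InChIKey forces NP
  ref_id <- ref
  key <- out$inchikey[out$source_id == "m_novel"]
  ref_id$np_inchikeys <- sort(union(ref$np_inchikeys, key))
  out_id <- assign_status(u$recs, u$fcg, ref_id)
  expect_identical(out_id$status[out_id$source_id == "m_novel"], "NP")
})

test_that("the NP reference survives a JSON round trip", {
  u <- fx_universe()
  ref <- build_np_reference(u$np, u$catalog, u$cfg, fcg_table = u$np_fcg)
  f <- tempfile(fileext = ".json")
  write_np_reference(ref, f)
  back <- read_np_reference(f)
  expect_identical(back$np_inchikeys, ref$np_inchikeys)
  expect_identical(back$np_signatures, ref$np_signatures)
  expect_identical(back$fcg_compare_level, ref$fcg_compare_level)
})
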