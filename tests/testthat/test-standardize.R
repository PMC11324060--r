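# Standardization stage: table reading, racemization, salt stripping,
# deglycosylation, filters, deduplication and the chunked/timeout map.

test_that("SMILES-TSV reading keeps parseable rows and counts rejects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "a\tc1ccccc1", "b\tC1CC", "c\tCCO"), f)
  suppressMessages(recs <- read_molecule_table(f, "smiles-tsv"))
  expect_equal(nrow(recs), 2L)
  expect_equal(attr(recs, "n_rejected"), 1L)
  expect_equal(recs$source_id, c("a", "c"))
  expect_error(read_molecule_table(tempfile(), "smiles-tsv"), "not found")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "a\tC1CC"), f2)
  expect_error(suppressMessages(read_molecule_table(f2, "smiles-tsv")),
               "no parseable")
})

test_that("SDF reading yields one record per entry, duplicates retained", {
  sdf <- ChemmineR::smiles2sdf(c(m1 = "c1ccccc1", m2 = "CCO", m3 = "c1ccccc1"))
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  recs <- read_molecule_table(f, "sdf")
  expect_equal(nrow(recs), 3L)  # dedup is a separate, later step
})

test_that("standardization racemizes, strips salts and canonicalizes", {
  r1 <- standardize_structure("C[C@H](N)C(=O)O")
  r2 <- standardize_structure("CC(N)C(=O)O")
  expect_identical(r1$inchikey, r2$inchikey)
  expect_false(grepl("@", r1$smiles_std, fixed = TRUE))
  expect_match(r1$inchikey, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  # largest organic component: benzene retained over salt ions
  r3 <- standardize_structure("c1ccccc1.[Na+].[Cl-]")
  expect_identical(r3$smiles_std, "c1ccccc1")
  # canonical output independent of input atom order
  r4 <- standardize_structure("OC(=O)C(N)C")
  expect_identical(r4$smiles_std, r1$smiles_std)
  expect_error(standardize_structure("C1CC("), "failed")
})

test_that("standardization is idempotent", {
  for (smi in c("C[C@H](N)C(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
                "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O")) {
    once <- standardize_structure(smi)
    twice <- standardize_structure(once$smiles_std)
    expect_identical(twice$smiles_std, once$smiles_std, info = smi)
    expect_identical(twice$inchikey, once$inchikey, info = smi)
  }
})

test_that("deglycosylation removes terminal sugars iteratively", {
  # salicin: the aglycone is saligenin; oracle is manual removal of the
  # pyranose atom set from the drawn structure
  expect_identical(deglycosylate("OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O"),
                   ob_canonical_smiles("OCc1ccccc1O"))
  # no sugar: unchanged
  expect_identical(deglycosylate("OC1CCCC1"),
                   ob_canonical_smiles("OC1CCCC1"))
  # diglycoside: both terminal units removed one after the other
  dig <- "OCC1OC(Oc2ccccc2)C(O)C(O)C1OC1OC(CO)C(O)C(O)C1O"
  expect_identical(deglycosylate(dig), ob_canonical_smiles("Oc1ccccc1"))
  # free glucose has no aglycone and stays untouched
  glc <- "OCC1OC(O)C(O)C(O)C1O"
  expect_identical(deglycosylate(glc), ob_canonical_smiles(glc))
})

test_that("structural filters require a ring and MW below 1000", {
  expect_false(apply_filters(0L, 100))            # acyclic
  expect_false(apply_filters(1L, 1050))           # too heavy
  expect_true(apply_filters(1L, 100.16))          # cyclohexanol
  expect_false(apply_filters(NA_integer_, 100))   # failed standardization
})

test_that("deduplication keeps first occurrence per racemic InChIKey", {
  recs <- do.call(rbind, lapply(1:3, function(i) {
    r <- fraggraph:::.fg_empty_molecule_table(1L)
    r$source_id <- paste0("m", i)
    r
  }))
  recs$inchikey <- c("KEY1", "KEY2", "KEY1")
  out <- deduplicate(recs)
  expect_equal(out$source_id, c("m1", "m2"))
  expect_equal(attr(out, "n_duplicates"), 1L)
  # two enantiomers collapse onto one record through the racemic key
  enant <- standardize_structures(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
  expect_equal(length(unique(enant$inchikey)), 1L)
  empty <- deduplicate(fraggraph:::.fg_empty_molecule_table(0L))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_duplicates"), 0L)
})

test_that("chunked_map results are independent of chunk size", {
  op <- function(x) x^2 + 1
  records <- as.list(1:100)
  outs <- lapply(c(1L, 7L, 100L), function(cs)
    chunked_map(records, op, fg_config(chunk_size = cs)))
  expect_identical(outs[[1]], outs[[2]])
  expect_identical(outs[[1]], outs[[3]])
  expect_identical(outs[[1]], lapply(records, op))
  expect_identical(chunked_map(list(), op, fg_config()), list())
})

test_that("chunked_map marks timed-out records and completes the run", {
  op <- function(x) {
    if (x == 2L) { s <- 0; repeat { s <- s + 1 } }   # busy loop, never ends
    x
  }
  res <- chunked_map(as.list(1:3), op, fg_config(timeout_s = 0.2))
  expect_identical(res[[1]], 1L)
  expect_s3_class(res[[2]], "fg_timeout")
  expect_identical(res[[3]], 3L)
})
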