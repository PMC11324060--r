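# Library aggregation, scaffold-based subset selection and PAINS triage.

fx_mini_status <- function() {
  n <- 20L
  recs <- fraggraph:::.fg_empty_molecule_table(n)
  recs$source_id <- sprintf("m%02d", seq_len(n))
  recs$status <- c(rep("PNP", 8), rep("NPL", 2), rep("NonPNP", 10))
  # 4 typed edges among the PNP molecules: 3 cm + 1 fe
  fcg <- data.frame(
    source_id = c("m01", "m02", "m03", "m04"),
    inchikey = paste0("K", 1:4), fcg_index = 1L,
    signature = c("1:2:cm", "1:2:cm", "1:3:cm", "2:3:fe"),
    n_edges = 1L,
    edges = c("1:2:cm", "1:2:cm", "1:3:cm", "2:3:fe"),
    stringsAsFactors = FALSE)
  list(recs = recs, fcg = fcg)
}

test_that("summary counts statuses and edge-type distributions", {
  x <- fx_mini_status()
  s <- summarize_library(x$recs, x$fcg)
  expect_equal(as.integer(s$status_counts),
               c(PNP = 8L, NPL = 2L, NP = 0L, NonPNP = 10L),
               ignore_attr = TRUE)
  expect_equal(s$ctype_percent[["cm"]], 75)
  expect_equal(s$ctype_percent[["fe"]], 25)
  expect_equal(sum(s$ctype_percent), 100, tolerance = 0.1)
  expect_equal(s$ctype_ratio[["cm"]], 100)
  expect_equal(s$ctype_ratio[["fe"]], 100 / 3, tolerance = 1e-9)
  # most frequent combination: 1:2:cm in 2 of 4 PNP molecules with edges
  expect_equal(s$top_combinations$combination[1], "1:2:cm")
  expect_equal(s$top_combinations$percent[1], 50)
})

test_that("ctype ratios are invariant to library duplication", {
  x <- fx_mini_status()
  recs2 <- rbind(x$recs, within(x$recs, source_id <- paste0(source_id, "b")))
  fcg2 <- rbind(x$fcg, within(x$fcg, source_id <- paste0(source_id, "b")))
  s1 <- summarize_library(x$recs, x$fcg)
  s2 <- summarize_library(recs2, fcg2)
  expect_equal(s1$ctype_ratio, s2$ctype_ratio)
  expect_equal(s1$ctype_percent, s2$ctype_percent)
})

test_that("empty summaries warn instead of failing", {
  expect_warning(s <- summarize_library(fraggraph:::.fg_empty_molecule_table(0L),
                                        fx_mini_status()$fcg), "empty")
  expect_equal(s$n_molecules, 0L)
})

test_that("subset selection reproduces with a fixed seed and filters groups", {
  grp <- fx_scaffold_groups()
  sel1 <- select_cpa_subset(grp, seed = 1L)
  sel2 <- select_cpa_subset(grp, seed = 1L)
  expect_identical(sel1$source_id, sel2$source_id)
  expect_equal(nrow(sel1), 250L * 4L)
  expect_equal(length(unique(sel1$scaffold_inchikey)), 250L)
  expect_true(all(table(sel1$scaffold_inchikey) == 4L))
  sel3 <- select_cpa_subset(grp, seed = 2L)
  expect_false(identical(sel1$source_id, sel3$source_id))
  # every selected scaffold has exactly 17 heavy atoms
  ha <- vapply(unique(sel1$scaffold_smiles),
               function(s) mol_from_smiles(s)$n_atoms, integer(1))
  expect_true(all(ha == 17L))
})

test_that("groups below the size minimum or off the size target are excluded", {
  grp <- fx_scaffold_groups()
  # trim the first 30 scaffold groups to 3 members: they must never appear
  small <- unique(grp$scaffold_ref)[1:30]
  trimmed <- do.call(rbind, lapply(split(grp, grp$scaffold_ref), function(g) {
    if (g$scaffold_ref[1] %in% small) g[1:3, , drop = FALSE] else g
  }))
  sel <- select_cpa_subset(trimmed, seed = 1L)
  expect_false(any(sel$scaffold_ref %in% small))
  # a 16-heavy-atom scaffold requirement cannot be satisfied by this set
  expect_error(select_cpa_subset(grp, scaffold_heavy_atoms = 16L),
               "qualifying")
})

test_that("PAINS triage removes flagged substructures only", {
  recs <- fraggraph:::.fg_empty_molecule_table(3L)
  recs$source_id <- c("rhod", "clean", "quin")
  recs$smiles_std <- c("O=C1CSC(=S)N1Cc1ccccc1",  # N-benzyl rhodanine
                       "OC1CCCCC1",               # cyclohexanol
                       "O=C1C=CC(=O)C=C1")        # para-quinone
  out <- suppressMessages(pains_filter(recs))
  expect_identical(out$source_id, "clean")
  removed <- attr(out, "removed")
  expect_setequal(removed$source_id, c("rhod", "quin"))
  expect_identical(removed$pattern[removed$source_id == "rhod"], "rhodanine")
  empty <- pains_filter(fraggraph:::.fg_empty_molecule_table(0L))
  expect_equal(nrow(empty), 0L)
})
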