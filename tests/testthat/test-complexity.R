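# Spatial score (SPS / nSPS): per-atom terms and parity with the published
# reference implementation on a fixed 25-molecule panel (values frozen from
# that implementation; standardized racemic SMILES).

fx_nsps_panel <- function() {
  utils::read.delim(system.file("extdata", "nsps_reference_panel.tsv",
                                package = "fraggraph"),
                    stringsAsFactors = FALSE)
}

test_that("nSPS matches the reference implementation on the fixed panel", {
  panel <- fx_nsps_panel()
  expect_equal(nrow(panel), 25L)
  for (i in seq_len(nrow(panel))) {
    got <- nsps(panel$smiles[i])
    expect_lt(abs(got$sps - panel$sps[i]), 1e-9)
    expect_lt(abs(got$nsps - panel$nsps[i]), 1e-9)
  }
})

test_that("per-atom terms follow the published scheme", {
  benz <- atom_spatial_score("c1ccccc1")
  # aromatic sp2 carbon, 2 neighbors, no ring promotion: 2 * 1 * 1 * 4
  expect_true(all(benz$score == 8))
  cyhx <- atom_spatial_score("C1CCCCC1")
  # saturated ring carbon: 3 * 1 * 2 * 4 = 24, strictly above aromatic
  expect_true(all(cyhx$score == 24))
  expect_gt(cyhx$score[1], benz$score[1])
  # a potential stereocenter doubles the atom score
  chiral <- atom_spatial_score("CC(F)Cl")
  achiral <- atom_spatial_score("CC(F)F")
  expect_equal(chiral$s_term[2], 2)
  expect_equal(achiral$s_term[2], 1)
  expect_gte(sum(chiral$score), sum(achiral$score))
})

test_that("nSPS is invariant to the SMILES rendering", {
  pairs <- list(c("c1ccncc1CC(N)C(=O)O", "OC(=O)C(N)Cc1ccncc1"),
                c("CC(=O)Oc1ccccc1C(=O)O", "O=C(O)c1ccccc1OC(C)=O"),
                c("CN1CCCC1c1cccnc1", "c1cccnc1C1CCCN1C"))
  for (p in pairs) {
    expect_equal(nsps(p[1])$nsps, nsps(p[2])$nsps, tolerance = 1e-12)
  }
})

test_that("potential E/Z double bonds and sulfoxides gain the stereo term", {
  butene <- atom_spatial_score("CC=CC")
  expect_equal(butene$s_term, c(1, 2, 2, 1))
  isobutene <- atom_spatial_score("CC(=C)C")  # symmetric end: no E/Z
  expect_true(all(isobutene$s_term == 1))
  sulfox <- atom_spatial_score("CS(=O)c1ccccc1")
  expect_equal(sulfox$s_term[2], 2)
})

test_that("nsps rejects empty structures", {
  expect_error(nsps(""), "empty")
})
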