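# Molecular graph model: SMILES parsing, implicit hydrogens, ring
# perception, molecular weight, and writer round trips.

test_that("parser derives atom counts, rings and molecular weight correctly", {
  cases <- list(
    list(smi = "c1ccncc1", atoms = 6L, rings = 1L, mw = 79.10),
    list(smi = "Cn1cnc2c1c(=O)n(C)c(=O)n2C", atoms = 14L, rings = 2L, mw = 194.19),
    list(smi = "c1ccsc1", atoms = 5L, rings = 1L, mw = 84.14),
    list(smi = "c1cc[nH]c1", atoms = 5L, rings = 1L, mw = 67.09),
    list(smi = "CC(=O)Oc1ccccc1C(=O)O", atoms = 13L, rings = 1L, mw = 180.16),
    list(smi = "C1CC2CCC1CC2", atoms = 8L, rings = 2L, mw = 110.20),
    list(smi = "c1ccccc1.[Na+].[Cl-]", atoms = 8L, rings = 1L, mw = 136.56))
  for (cs in cases) {
    m <- mol_from_smiles(cs$smi)
    expect_equal(m$n_atoms, cs$atoms, info = cs$smi)
    expect_equal(m$n_rings, cs$rings, info = cs$smi)
    expect_equal(m$mw, cs$mw, tolerance = 5e-4, info = cs$smi)
  }
})

test_that("writer round-trips through Open Babel canonicalization", {
  smis <- c("c1ccncc1", "CC(N)C(=O)O", "c1ccc(cc1)c1ccccc1",
            "O=C1c2ccccc2-c2c1cccc2", "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O",
            "C[N+](C)(C)C", "CC(=O)[O-]", "c1ccc2c(c1)cc[nH]2",
            "CS(=O)(=O)c1ccccc1", "C%10CCCCC%10", "N#Cc1ccccc1",
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  for (s in smis) {
    written <- mol_to_smiles(mol_from_smiles(s))
    expect_identical(ob_canonical_smiles(written), ob_canonical_smiles(s),
                     info = s)
  }
})

test_that("stereo descriptors are accepted and dropped", {
  m1 <- mol_from_smiles("C[C@H](N)C(=O)O")
  m2 <- mol_from_smiles("CC(N)C(=O)O")
  expect_equal(m1$n_atoms, m2$n_atoms)
  expect_identical(ob_canonical_smiles(mol_to_smiles(m1)),
                   ob_canonical_smiles(mol_to_smiles(m2)))
})

test_that("biaryl bonds written without a dash are demoted to single", {
  m <- mol_from_smiles("c1ccc(cc1)c1ccccc1")  # Open Babel writes no dash
  expect_equal(m$n_rings, 2L)
  inter <- m$bonds[!m$ring_bond, , drop = FALSE]
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$order, 1L)
})

test_that("malformed SMILES raise errors", {
  expect_error(mol_from_smiles("C1CC"), "ring")
  expect_error(mol_from_smiles("C(C"), "parenthes")
  expect_error(mol_from_smiles("[Qq]"), "element|bracket")
  expect_error(mol_from_smiles(""), "empty")
})

test_that("explicit-hydrogen atoms fold into neighbor H counts", {
  m <- mol_from_smiles("[H]C([H])([H])O")
  expect_equal(m$n_atoms, 2L)
  expect_equal(sort(m$nh), c(1L, 3L))
})
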