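# Chemical space: physicochemical profiles, fingerprints, scaffolds, MCS,
# embedding.

test_that("physicochemical profile is correct on reference molecules", {
  p <- physchem_profile(c("C", "c1ccccc1", "CCc1ccccc1", "CCCCCC"),
                        ids = c("methane", "benzene", "ethylbenzene",
                                "hexane"))
  expect_true(all(p$valid))
  expect_equal(p$rotatable_bonds, c(0L, 0L, 1L, 3L))
  expect_equal(p$rings, c(0L, 1L, 1L, 0L))
  expect_equal(p$TPSA[p$compound_id == "benzene"], 0)
  expect_gt(p$MW[p$compound_id == "hexane"],
            p$MW[p$compound_id == "methane"])
})

test_that("single-atom molecules are profiled without error", {
  p <- physchem_profile("C")
  expect_true(p$valid)
  expect_equal(p$rings, 0L)
})

test_that("unparseable structures are flagged, not dropped", {
  p <- physchem_profile(c("c1ccccc1", "not_a_smiles(((", ""))
  expect_equal(nrow(p), 3)
  expect_equal(p$valid, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(p$MW[!p$valid])))
})

test_that("Murcko scaffold strips side chains but keeps ring linkers", {
  expect_equal(murcko_scaffold("CCc1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("O=C(C)Nc1ccccc1"), "c1ccccc1")
  expect_equal(murcko_scaffold("c1ccccc1"), "c1ccccc1")
  # benzophenone: the carbonyl linker including its oxygen is scaffold
  bp <- murcko_scaffold("O=C(c1ccccc1)c2ccccc2")
  expect_equal(bp, murcko_scaffold(bp))
  expect_true(grepl("O", bp))
})

test_that("acyclic molecules have an empty scaffold", {
  expect_equal(murcko_scaffold("CCCCCC"), "")
  expect_equal(murcko_scaffold("CCO"), "")
  expect_equal(murcko_scaffold("C"), "")
})

test_that("scaffold extraction is idempotent", {
  smis <- c("CCc1ccccc1", "O=C(c1ccccc1)Nc1ccc(CC)cc1",
            "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(cc1)C(=O)Nc2ccccc2",
            "c1ccc2[nH]ccc2c1", "Cn1ccc2ccccc21",
            toy_smiles_library(20, seed = 6))
  for (s in smis) {
    sc <- murcko_scaffold(s)
    expect_equal(murcko_scaffold(sc), sc)
  }
})

test_that("N-substituted and NH heteroaromatics share one scaffold", {
  expect_equal(murcko_scaffold("Cn1ccc2ccccc21"),
               murcko_scaffold("c1ccc2[nH]ccc2c1"))
})

test_that("scaffold overlap of identical sets is complete", {
  set <- c("CCc1ccccc1", "c1ccc2ccccc2c1")
  ov <- scaffold_overlap(set, set)
  expect_equal(ov$summary_a$scaffolds, ov$summary_b$scaffolds)
  expect_equal(sort(ov$shared), sort(ov$summary_a$scaffolds))
})

test_that("disjoint scaffold sets share nothing", {
  ov <- scaffold_overlap("CCc1ccccc1", "C1CCNCC1")
  expect_equal(length(ov$shared), 0L)
})

test_that("fingerprints of a molecule and itself have Tanimoto 1", {
  fp <- morgan_fp(c("c1ccccc1", "CC(=O)Nc1ccccc1", "CCO"))
  expect_true(all(rowSums(fp$bits) > 0))
  self_sim <- cross_max_similarity(fp, fp)
  expect_equal(unname(self_sim), rep(1, 3))
})

test_that("Tanimoto is symmetric, bounded, and 0 for the empty pair", {
  set.seed(9)
  a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_gte(tanimoto(a, b), 0)
  expect_lte(tanimoto(a, b), 1)
  expect_equal(tanimoto(a, a), ifelse(sum(a) > 0, 1, 0))
  expect_equal(tanimoto(numeric(8), numeric(8)), 0)
})

test_that("cross-set maximum similarity matches a brute-force loop", {
  fps_a <- morgan_fp(toy_smiles_library(6, seed = 2))
  fps_b <- morgan_fp(toy_smiles_library(5, seed = 3))
  fast <- cross_max_similarity(fps_a, fps_b)
  slow <- vapply(seq_len(nrow(fps_a$bits)), function(i)
    max(vapply(seq_len(nrow(fps_b$bits)), function(j)
      tanimoto(fps_a$bits[i, ], fps_b$bits[j, ]), numeric(1))),
    numeric(1))
  expect_equal(unname(fast), slow, tolerance = 1e-12)
})

test_that("strict-aromatic MCS never exceeds relaxed MCS", {
  smis <- toy_smiles_library(5, seed = 8)
  mols <- parse_smiles(smis)
  for (i in 1:4) {
    strict <- mcs_size(mols[[i]], mols[[i + 1]], mode = "strict_aromatic")
    relaxed <- mcs_size(mols[[i]], mols[[i + 1]], mode = "relaxed")
    expect_lte(strict$size, relaxed$size)
  }
})

test_that("MCS distinguishes aromatic from saturated rings", {
  mols <- parse_smiles(c("c1ccccc1", "C1CCCCC1"))
  strict <- mcs_size(mols[[1]], mols[[2]], mode = "strict_aromatic")
  relaxed <- mcs_size(mols[[1]], mols[[2]], mode = "relaxed")
  expect_equal(strict$size, 0L)
  expect_equal(relaxed$size, 6L)
})

test_that("MCS of a molecule with itself is the whole molecule", {
  mol <- parse_smiles("CCc1ccccc1")[[1]]
  res <- mcs_size(mol, mol, mode = "strict_aromatic")
  expect_equal(res$size, mol$n_atoms)
})

test_that("MCS is symmetric in its arguments", {
  mols <- parse_smiles(c("CCc1ccccc1", "CC(=O)Nc1ccccc1"))
  ab <- mcs_size(mols[[1]], mols[[2]])
  ba <- mcs_size(mols[[2]], mols[[1]])
  expect_equal(ab$size, ba$size)
})

test_that("shared-substructure pairs honour the minimum atom threshold", {
  smis <- toy_smiles_library(4, seed = 5)
  res <- shared_substructure_pairs(smis, smis, min_atoms = 3)
  expect_true(all(res$n_matched_atoms > 3))
})

test_that("2-D embedding places duplicate compounds at the same point", {
  smis <- c("CCc1ccccc1", "CCc1ccccc1", "CCO", "c1ccncc1")
  fp <- morgan_fp(smis, ids = paste0("c", 1:4))
  emb <- embed_chemical_space(fp, seed = 3)
  d12 <- sqrt((emb$x[1] - emb$x[2])^2 + (emb$y[1] - emb$y[2])^2)
  d13 <- sqrt((emb$x[1] - emb$x[3])^2 + (emb$y[1] - emb$y[3])^2)
  expect_lt(d12, 1e-8)
  expect_gt(d13, 0.01)
})

test_that("embedding is deterministic", {
  fp <- morgan_fp(toy_smiles_library(5, seed = 4))
  e1 <- embed_chemical_space(fp, seed = 1)
  e2 <- embed_chemical_space(fp, seed = 1)
  expect_equal(e1, e2)
})
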