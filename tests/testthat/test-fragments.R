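test_that("fragment counts match the brute-force subgraph oracle on small molecules", {
  for (nm in names(fixture_smiles)) {
    mol <- parse_smiles(fixture_smiles[[nm]])
    if (nrow(mol$atoms) > 8) next
    for (range in list(c(1, 3), c(2, 4), c(1, nrow(mol$atoms)))) {
      got <- enumerate_fragments(mol, range[1], range[2])
      want <- oracle_fragments(mol, range[1], range[2])
      expect_identical(frag_set_string(got), frag_set_string(want),
                       label = sprintf("%s sizes %d-%d", nm, range[1], range[2]))
    }
  }
})

test_that("anchor counts: propane sizes 1-3 gives 6, benzene ring once, small single atom none", {
  expect_length(enumerate_fragments(parse_smiles("CCC"), 1, 3), 6L)
  expect_length(enumerate_fragments(parse_smiles("c1ccccc1"), 6, 6), 1L)
  expect_length(enumerate_fragments(parse_smiles("C"), 4, 9), 0L)
  expect_error(enumerate_fragments(parse_smiles("CC"), 1, 13), "guard")
})

test_that("fragment keys respond to exactly the flagged properties", {
  eth <- parse_smiles("CCO")
  co_frag <- c(2L, 3L)   # the C-O fragment
  a_only <- fragment_key(eth, co_frag, distinction_flags(A = TRUE))
  a_h <- fragment_key(eth, co_frag, distinction_flags(A = TRUE, H = TRUE))
  expect_false(identical(a_only, a_h))
  # without the H flag, CH2-O in ethanol keys like CH3-O in methanol-ether
  met <- parse_smiles("CO")
  expect_identical(fragment_key(met, c(1L, 2L), distinction_flags(A = TRUE)),
                   a_only)
  expect_false(identical(
    fragment_key(met, c(1L, 2L), distinction_flags(A = TRUE, H = TRUE)), a_h))
})

test_that("keys are invariant under atom renumbering", {
  mol <- parse_smiles("CC(C)C(=O)O")
  fl <- distinction_flags(A = TRUE, B = TRUE, C = TRUE, H = TRUE)
  frag <- c(2L, 4L, 5L, 6L)
  base <- fragment_key(mol, frag, fl)
  set.seed(13)
  for (i in 1:20) {
    perm <- sample(nrow(mol$atoms))
    pm <- permute_molecule(mol, perm)
    expect_identical(fragment_key(pm, sort(perm[frag]), fl), base)
  }
})

test_that("a 6-atom symmetric fragment yields one unique key over 20 renumberings", {
  benz <- parse_smiles("c1ccccc1")
  fl <- distinction_flags(A = TRUE, B = TRUE)
  keys <- character(0)
  set.seed(17)
  for (i in 1:20) {
    pm <- permute_molecule(benz, sample(6))
    keys <- c(keys, fragment_key(pm, 1:6, fl))
  }
  expect_length(unique(keys), 1L)
})

test_that("distinct graphs get distinct keys under full flags", {
  fl <- distinction_flags(A = TRUE, B = TRUE, C = TRUE, H = TRUE)
  nbutane <- parse_smiles("CCCC")
  isobutane <- parse_smiles("CC(C)C")
  expect_false(identical(fragment_key(nbutane, 1:4, fl),
                         fragment_key(isobutane, 1:4, fl)))
  propene <- parse_smiles("C=CC")
  propane <- parse_smiles("CCC")
  expect_false(identical(fragment_key(propene, 1:3, distinction_flags(A = TRUE, B = TRUE)),
                         fragment_key(propane, 1:3, distinction_flags(A = TRUE, B = TRUE))))
  # without the bond flag the two propyl skeletons with A-only flags merge
  expect_identical(fragment_key(propene, 1:3, distinction_flags(A = TRUE)),
                   fragment_key(propane, 1:3, distinction_flags(A = TRUE)))
})

test_that("crc32 matches known reference checksums", {
  # reference values from the IEEE 802.3 CRC-32 ('cksum -o3'/zlib convention)
  expect_equal(crc32(""), 0)
  expect_equal(crc32("a"), 3904355907)
  expect_equal(crc32("abc"), 891568578)
  expect_equal(crc32("123456789"), 3421780262)
})

test_that("hologram counts conserve the number of fragment occurrences", {
  mol <- parse_smiles("CC(C)C(=O)O")
  for (L in c(53L, 83L)) {
    h <- build_hologram(mol, L, distinction_flags(A = TRUE), 1, 4)
    expect_equal(sum(h$counts), length(enumerate_fragments(mol, 1, 4)))
    expect_equal(h$length, L)
    expect_true(all(h$counts >= 0))
  }
})

test_that("holograms are invariant under atom reordering", {
  g <- gen_coumarin_smiles(10, seed = 23)
  mols <- attr(g, "molecules")
  fl <- distinction_flags(A = TRUE, DA = TRUE)
  set.seed(29)
  mismatches <- 0L
  for (mol in mols) {
    ref <- build_hologram(mol, 61, fl, 4, 6)$counts
    for (i in 1:5) {
      pm <- permute_molecule(mol, sample(nrow(mol$atoms)))
      if (!identical(build_hologram(pm, 61, fl, 4, 6)$counts, ref))
        mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("molecules differing by one substituent give different holograms", {
  coum <- coumarin_core()
  methyl <- parse_smiles("O=C1C=C(C)c2ccccc2O1")   # 4-methylcoumarin
  fl <- distinction_flags(A = TRUE, C = TRUE)
  h1 <- build_hologram(coum, 83, fl, 4, 7)
  h2 <- build_hologram(methyl, 83, fl, 4, 7)
  expect_gte(sum(h1$counts != h2$counts), 1L)
})
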