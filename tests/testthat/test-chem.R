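# Structure handling: standardisation, fingerprints, similarity, scaffolds,
# duplicate detection.

test_that("standardisation canonicalises, strips salts and is idempotent", {
  expect_equal(standardize_structure("CCO"), "CCO")
  expect_equal(standardize_structure("OCC"), "CCO")
  expect_equal(standardize_structure("CCO.Cl"), "CCO")
  # counter-ion dropped and carboxylate neutralised
  expect_equal(standardize_structure("CC(=O)[O-].[Na+]"), "CC(=O)O")
  # idempotence over the whole fixture set
  once <- fixture_standardized()
  expect_equal(standardize_structure(once), once)
})

test_that("unparseable SMILES raise a structured parse error", {
  err <- tryCatch(standardize_structure("not_a_smiles"),
                  zfscreen_parse_error = identity)
  expect_s3_class(err, "zfscreen_parse_error")
  expect_match(conditionMessage(err), "not_a_smiles")
})

test_that("fingerprints are deterministic functions of the structure", {
  expect_identical(compute_fingerprint("CCO")$bits,
                   compute_fingerprint("OCC")$bits)
  # aromatic and aliphatic six-rings are different substructure environments
  expect_false(identical(compute_fingerprint("c1ccccc1")$bits,
                         compute_fingerprint("C1CCCCC1")$bits))
  fps <- fixture_fingerprints()
  expect_true(all(vapply(fps, function(f) length(f$bits) > 0, logical(1))))
  expect_true(all(vapply(fps, function(f) all(f$bits >= 0 & f$bits < f$n_bits),
                         logical(1))))
})

test_that("tanimoto follows set arithmetic, symmetry and bounds", {
  mk <- function(bits) zfscreen:::new_fingerprint(bits, 2048L, 2L)
  expect_equal(tanimoto(mk(c(1, 5, 9)), mk(c(1, 5, 9))), 1.0)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0.0)
  expect_equal(tanimoto(mk(1:3), mk(2:4)), 0.5)
  expect_warning(z <- tanimoto(mk(integer(0)), mk(integer(0))), "empty")
  expect_equal(z, 0)
  # symmetry and bounds across the fixture set
  fps <- fixture_fingerprints()
  idx <- seq(1, length(fps), by = 3)
  for (i in idx) {
    expect_equal(tanimoto(fps[[i]], fps[[i]]), 1.0)
    for (j in idx) {
      tij <- tanimoto(fps[[i]], fps[[j]])
      expect_true(tij >= 0 && tij <= 1)
      expect_equal(tij, tanimoto(fps[[j]], fps[[i]]))
    }
  }
})

test_that("similarity_matrix matches the brute-force double loop", {
  smis <- fixture_standardized()
  m <- similarity_matrix(smis)
  expect_equal(dim(m), c(50L, 50L))
  expect_equal(unname(diag(m)), rep(1, 50))
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  oracle <- brute_similarity_matrix(fixture_fingerprints())
  expect_equal(unclass(m), oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("similarity_matrix handles degenerate and duplicate inputs", {
  one <- similarity_matrix(c(x = "CCO"))
  expect_equal(unclass(one), matrix(1, 1, 1, dimnames = list("x", "x")),
               ignore_attr = TRUE)
  dup <- similarity_matrix(c(a = "CCO", b = "OCC"))
  expect_equal(dup["a", "b"], 1.0)
  err <- tryCatch(similarity_matrix(c(ok = "CCO", bad = "xxxx")),
                  zfscreen_parse_error = identity)
  expect_s3_class(err, "zfscreen_parse_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("Bemis-Murcko scaffolds prune side chains and keep linkers", {
  benzene <- bemis_murcko_scaffold("c1ccccc1")
  expect_equal(bemis_murcko_scaffold("Cc1ccccc1"), benzene)
  expect_equal(bemis_murcko_scaffold("CCO"), "")
  # 1,2-diphenylethane keeps both rings plus the two-carbon linker
  dpe <- bemis_murcko_scaffold("c1ccccc1CCc1ccccc1")
  expect_equal(dpe, standardize_structure("c1ccccc1CCc1ccccc1"))
  # ester side chain is removed entirely, exocyclic ring ketone is kept
  expect_equal(bemis_murcko_scaffold("COC(=O)c1ccccc1"), benzene)
  expect_equal(bemis_murcko_scaffold("O=C1CCCCC1"),
               standardize_structure("O=C1CCCCC1"))
})

test_that("scaffold_summary counts conserve compounds", {
  s <- scaffold_summary(c(tol = "Cc1ccccc1", etb = "CCc1ccccc1",
                          phe = "Oc1ccccc1"))
  expect_equal(s$n_scaffolds, 1L)
  expect_equal(s$n_singleton_scaffolds, 0L)
  expect_equal(sort(s$scaffold_to_members[[1]]), c("etb", "phe", "tol"))

  s2 <- scaffold_summary(c(tol = "Cc1ccccc1", chx = "OC1CCCCC1"))
  expect_equal(s2$n_scaffolds, 2L)
  expect_equal(s2$n_singleton_scaffolds, 2L)

  s0 <- scaffold_summary(character(0))
  expect_equal(s0$n_compounds, 0L)
  expect_equal(s0$n_scaffolds, 0L)

  # conservation over a mixed fixture subset (includes acyclic compounds)
  smis <- fixture_standardized()[1:30]
  s3 <- scaffold_summary(smis)
  expect_equal(sum(lengths(s3$scaffold_to_members)) + s3$n_acyclic +
                 s3$n_parse_failed, s3$n_compounds)
  expect_lte(s3$n_singleton_scaffolds, s3$n_scaffolds)
})

test_that("find_duplicates equals brute-force all-pairs key comparison", {
  mk_lib <- function(ids, keys) {
    data.frame(compound_id = ids, identity_key = keys,
               stringsAsFactors = FALSE)
  }
  # same molecule under different SMILES spellings across the libraries
  a <- compound_library(data.frame(
    library_id = "A", plate = "A01", well = c("A02", "A03"),
    name = c("etoh", "benz"), smiles = c("OCC", "c1ccccc1")))
  b <- compound_library(data.frame(
    library_id = "B", plate = "B01", well = c("A02", "A03"),
    name = c("ethanol", "phenol"), smiles = c("CCO", "Oc1ccccc1")))
  d <- find_duplicates(a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$id_a, a$compound_id[1])

  # enantiomers carry different stereo layers, so no pair
  ena <- compound_library(data.frame(
    library_id = "A", plate = "P1", well = "A02", name = "R",
    smiles = "C[C@H](N)C(=O)O"))
  enb <- compound_library(data.frame(
    library_id = "B", plate = "P1", well = "A02", name = "S",
    smiles = "C[C@@H](N)C(=O)O"))
  expect_equal(nrow(find_duplicates(ena, enb)), 0L)

  # brute-force comparison on a synthetic 200-key instance
  set.seed(21)
  keys_a <- sprintf("KEY%03d", sample(150, 120, replace = TRUE))
  keys_b <- sprintf("KEY%03d", sample(150, 80, replace = TRUE))
  la <- mk_lib(sprintf("a%03d", seq_along(keys_a)), keys_a)
  lb <- mk_lib(sprintf("b%03d", seq_along(keys_b)), keys_b)
  got <- find_duplicates(la, lb)
  want <- list()
  for (i in seq_along(keys_a)) {
    for (j in seq_along(keys_b)) {
      if (keys_a[i] == keys_b[j]) {
        want[[length(want) + 1]] <- c(la$compound_id[i], lb$compound_id[j])
      }
    }
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$id_a, got$id_b),
                  paste(want[, 1], want[, 2]))
  # deterministic order: sorted by key
  expect_false(is.unsorted(got$identity_key))

  # null identity keys are skipped with a warning
  la$identity_key[1] <- NA
  expect_warning(find_duplicates(la, lb), "skipped")
})
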