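test_that("canonicalization gives one identity per molecule", {
  a <- canonicalize("OCC")
  b <- canonicalize("CCO")
  expect_identical(a$canonical_form, b$canonical_form)
  expect_false(canonicalize("C1CC1")$canonical_form ==
                 canonicalize("CCC")$canonical_form)
  expect_true(abs(canonicalize("C")$mol_weight - 16.04) < 0.01)
  # canonicalizing a canonical form is idempotent
  expect_identical(canonicalize(a$canonical_form)$canonical_form,
                   a$canonical_form)
})

test_that("invalid structures are rejected with informative errors", {
  expect_error(canonicalize("C.C"), "disconnected")
  expect_error(canonicalize("xyz99"), "could not be parsed")
  expect_error(canonicalize("C(C)(C)(C)(C)C"), "valence")
  expect_error(canonicalize(""), "empty")
})

test_that("fingerprints are deterministic and canonical-invariant", {
  for (kind in fingerprint_kinds()$kind) {
    f1 <- fingerprint("CCO", kind)
    f2 <- fingerprint("OCC", kind)
    expect_identical(f1$bits, f2$bits)
    expect_identical(f1$length,
                     fingerprint_kinds()$nbits[fingerprint_kinds()$kind == kind])
    expect_lte(molmorph:::popcount_raw(f1$bits), f1$length)
  }
  expect_false(identical(fingerprint("CCO")$bits, fingerprint("CCN")$bits))
})

test_that("similarity matches hand-computable cases", {
  a <- fp_from_bits(c(1, 2))
  b <- fp_from_bits(c(1, 3))
  expect_equal(similarity(a, b, "TANIMOTO"), 1 / 3)
  expect_equal(similarity(a, b, "DICE"), 1 / 2)
  expect_equal(similarity(a, b, "COSINE"), 1 / 2)
  expect_equal(similarity(a, a), 1)
  expect_equal(similarity(fp_from_bits(1:4), fp_from_bits(5:8)), 0)
  # two empty vectors compare as identical
  e <- fp_from_bits(integer(0))
  expect_equal(similarity(e, e), 1)
  expect_error(similarity(a, fp_from_bits(1, nbits = 128)), "kind or length")
})

test_that("similarity agrees with the popcount oracle on random pairs", {
  withr::local_seed(42)
  for (i in 1:1000) {
    a_bits <- sample(64, sample(0:20, 1))
    b_bits <- sample(64, sample(0:20, 1))
    a <- fp_from_bits(a_bits); b <- fp_from_bits(b_bits)
    coeff <- sample(similarity_coefficients(), 1)
    s_ab <- similarity(a, b, coeff)
    expect_identical(s_ab, similarity(b, a, coeff))
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
    expect_equal(s_ab, naive_sim(a_bits, b_bits, 64, coeff))
  }
})

test_that("distance follows the target/decoy averaging rule", {
  dm <- distance_model("CCO")
  expect_equal(distance("OCC", dm), 0)
  d1 <- distance("CCN", dm)
  expect_gt(d1, 0); expect_lte(d1, 1)

  # constructed fingerprints: d_T = 0.4, decoy distances 0.6 and 0.2
  target <- fp_from_bits(1:5)
  mol <- fp_from_bits(c(1:3, 6, 7))          # tanimoto 3/7
  stopifnot(abs((1 - 3 / 7) - 0.5714286) < 1e-6)
  mk_model <- function(decoys) {
    structure(list(target_fp = target, decoy_fps = decoys,
                   coeff = "TANIMOTO", fp_kind = "TEST",
                   target_canonical = "x"), class = "distance_model")
  }
  d_t <- 1 - 3 / 7
  expect_equal(distance(mol, mk_model(list())), d_t)
  dec_far <- fp_from_bits(10:19)              # disjoint: distance 1
  dec_near <- fp_from_bits(c(1:3, 6, 7))      # identical: distance 0
  expect_equal(distance(mol, mk_model(list(dec_far))), (d_t + 1) / 2)
  expect_equal(distance(mol, mk_model(list(dec_far, dec_near))), d_t / 2)

  # adding a decoy shifts the distance by at most 0.5
  withr::local_seed(7)
  for (i in 1:50) {
    m <- fp_from_bits(sample(64, 10))
    dec <- fp_from_bits(sample(64, 10))
    base <- distance(m, mk_model(list()))
    with_dec <- distance(m, mk_model(list(dec)))
    expect_lte(abs(base - with_dec), 0.5)
  }
})
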