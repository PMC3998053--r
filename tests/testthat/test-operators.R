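test_that("site enumeration matches brute-force expectations", {
  expect_length(enumerate_sites("C", "RA"), 0)
  expect_length(enumerate_sites("CCC", "BC"), 1)
  expect_length(enumerate_sites("C1CC1", "BC"), 0)
  # methane with palette {C}: one attachable atom
  expect_length(enumerate_sites("C", "AA", palette = "C"), 1)
  # ethane admits no same-element mutation
  expect_length(enumerate_sites("CC", "MA", palette = "C"), 0)
  expect_error(enumerate_sites("CC", "XX"), "unknown operator")
})

test_that("operator applications produce the expected products", {
  bc <- enumerate_sites("CCC", "BC")[[1]]
  expect_identical(apply_operator("CCC", "BC", bc)$product$canonical_form,
                   "CC")

  m <- canonicalize("CCO")
  ma <- Filter(function(s) m$graph$elem[s$atom] == "O" && s$elem == "N",
               enumerate_sites(m, "MA", palette = c("C", "N")))
  expect_length(ma, 1)
  expect_identical(apply_operator(m, "MA", ma[[1]])$product$canonical_form,
                   canonicalize("CCN")$canonical_form)

  ab <- Filter(function(s) s$a == 1 && s$b == 4,
               enumerate_sites("CCCC", "AB"))
  expect_identical(apply_operator("CCCC", "AB", ab[[1]])$product$canonical_form,
                   canonicalize("C1CCC1")$canonical_form)

  ra <- Filter(function(s) m$graph$elem[s$atom] == "O",
               enumerate_sites(m, "RA"))
  expect_identical(apply_operator(m, "RA", ra[[1]])$product$canonical_form,
                   "CC")

  # interlaying O into the C-C bond gives dimethyl ether
  ia <- enumerate_sites("CC", "IA", palette = "O")
  expect_identical(apply_operator("CC", "IA", ia[[1]])$product$canonical_form,
                   "COC")

  # inapplicable sites raise, they are not skipped silently
  expect_error(apply_operator("CC", "RA", list(atom = 9)), "not applicable")
  expect_error(apply_operator("C1CC1", "BC", list(atom = 1)), "not applicable")
})

test_that("random morphing is seeded, bounded and failure-safe", {
  expect_null(random_morph("C", enabled = "RA"))
  for (s in c(1, 7, 99)) {
    expect_identical(random_morph("CC", enabled = "RA", seed = s)$product$canonical_form,
                     "C")
  }
  r1 <- random_morph("CC(=O)Oc1ccccc1C(=O)O", seed = 5, palette = c("C", "N"))
  r2 <- random_morph("CC(=O)Oc1ccccc1C(=O)O", seed = 5, palette = c("C", "N"))
  expect_identical(r1$product$canonical_form, r2$product$canonical_form)
  expect_identical(r1$site, r2$site)
})

test_that("generate_morphs deduplicates and excludes the parent", {
  g <- generate_morphs("C", n_gen = 100, enabled = "AA", palette = "C",
                       seed = 1)
  expect_identical(vapply(g, function(x) x$product$canonical_form, ""), "CC")
  expect_length(generate_morphs("CC", n_gen = 50, enabled = "MA",
                                palette = "C", seed = 1), 0)
  set <- generate_morphs("CC(=O)Oc1ccccc1C(=O)O", n_gen = 60, seed = 3,
                         palette = c("C", "N", "O"))
  cans <- vapply(set, function(x) x$product$canonical_form, "")
  expect_false(anyDuplicated(cans) > 0)
  expect_false(canonicalize("CC(=O)Oc1ccccc1C(=O)O")$canonical_form %in% cans)
  # bit-reproducible under a fixed seed
  set2 <- generate_morphs("CC(=O)Oc1ccccc1C(=O)O", n_gen = 60, seed = 3,
                          palette = c("C", "N", "O"))
  expect_identical(cans, vapply(set2, function(x) x$product$canonical_form, ""))
})

test_that("products obey valence, connectivity and single-edit semantics", {
  mols <- random_molecules(30, seed = 11)
  atom_delta <- c(AA = 1L, RA = -1L, AB = 0L, RB = 0L, MA = 0L, BR = 0L,
                  BC = -1L, IA = 1L)
  withr::local_seed(2)
  n_checked <- 0L
  for (rec in mols) {
    g <- rec$graph
    for (op in operator_kinds(include_optional = TRUE)) {
      sites <- molmorph:::sites_for_graph(g, op, c("C", "N", "O"))
      if (!length(sites)) next
      for (site in sites[sample.int(length(sites), min(3, length(sites)))]) {
        p <- molmorph:::apply_graph_op(g, op, site)
        ok <- molmorph:::mg_check(p, connectivity = TRUE)
        if (!isTRUE(ok)) fail(paste("invalid product:", ok))
        if (length(p$elem) - length(g$elem) != atom_delta[[op]]) {
          fail(paste("wrong atom-count delta for", op))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("inverse operators restore the parent", {
  mols <- random_molecules(20, seed = 23)
  withr::local_seed(3)
  for (rec in mols) {
    g <- rec$graph
    n <- length(g$elem)
    # AA then RA at the added atom
    aa <- enumerate_sites(rec, "AA", palette = "C")
    if (length(aa)) {
      p <- molmorph:::apply_graph_op(g, "AA", aa[[1]])
      back <- molmorph:::apply_graph_op(p, "RA", list(atom = n + 1L))
      expect_identical(back$elem, g$elem)
      expect_identical(sort(paste(back$bond[, 1], back$bond[, 2], back$bond[, 3])),
                       sort(paste(g$bond[, 1], g$bond[, 2], g$bond[, 3])))
    }
    # AB then RB at the created/incremented bond
    ab <- enumerate_sites(rec, "AB")
    if (length(ab)) {
      s <- ab[[sample.int(length(ab), 1)]]
      p <- molmorph:::apply_graph_op(g, "AB", s)
      k <- which(p$bond[, 1] == min(s$a, s$b) & p$bond[, 2] == max(s$a, s$b))
      back <- molmorph:::apply_graph_op(p, "RB", list(bond = k))
      expect_identical(sort(paste(back$bond[, 1], back$bond[, 2], back$bond[, 3])),
                       sort(paste(g$bond[, 1], g$bond[, 2], g$bond[, 3])))
    }
    # single-bond BC then IA with the removed element restores the molecule
    bc <- Filter(function(s) {
      nb <- molmorph:::mg_adjacency_list(g)[[s$atom]]
      all(g$bond[g$bond[, 1] == s$atom | g$bond[, 2] == s$atom, 3] == 1L)
    }, enumerate_sites(rec, "BC"))
    if (length(bc)) {
      s <- bc[[1]]
      elem_removed <- g$elem[s$atom]
      p <- molmorph:::apply_graph_op(g, "BC", s)
      nb <- sort(molmorph:::mg_adjacency_list(g)[[s$atom]])
      nb2 <- nb - (nb > s$atom)
      k <- which(p$bond[, 1] == nb2[1] & p$bond[, 2] == nb2[2])
      back <- molmorph:::apply_graph_op(p, "IA",
                                        list(bond = k, elem = elem_removed))
      expect_identical(
        unname(molmorph:::graphs_to_cansmi(list(back), "b")[["b"]]),
        rec$canonical_form
      )
    }
  }
})
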