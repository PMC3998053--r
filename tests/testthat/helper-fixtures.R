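# Shared fixtures: all built in code at test time.

# a few valid seed structures of varied chemistry
SEED_SMILES <- c(
  "CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2[nH]ccc2c1", "C1CCNCC1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CCCCCC", "c1ccncc1", "CC(=O)NC"
)

# drug-sized seeds used for benchmark emulation
DRUG_SEEDS <- c(
  "CN(C)CCCN1c2ccccc2CCc2ccccc12",                 # tricyclic amine
  "CC(C)NCC(O)COc1cccc2ccccc12",                   # aryloxypropanolamine
  "COc1cc2c(cc1OC)C(=O)C(CC1CCN(Cc3ccccc3)CC1)C2", # benzylpiperidine ketone
  "NC(=N)c1ccc(OCCCCCOc2ccc(C(=N)N)cc2)cc1",       # bis-amidine ether
  "Clc1ccc2c(c1)N(CCCN1CCN(C)CC1)c1ccccc1S2"       # phenothiazine-type
)

# Generate `n` random valid molecules (as mol_record) by 0-4 random edits
# from the seed set; heavy-atom count kept at or below `max_atoms`.
# Canonicalization happens in one batch at the end.
random_molecules <- function(n, seed = 1L, max_atoms = 20L) {
  withr::local_seed(seed)
  base_graphs <- lapply(SEED_SMILES, function(s) canonicalize(s)$graph)
  graphs <- list()
  guard <- 0L
  while (length(graphs) < n && guard < 20L * n) {
    guard <- guard + 1L
    g <- base_graphs[[sample.int(length(base_graphs), 1L)]]
    k <- sample(0:4, 1L)
    for (i in seq_len(k)) {
      cache <- new.env(parent = emptyenv())
      draw <- molmorph:::draw_graph_morph(g, operator_kinds(),
                                          c("C", "N", "O"), cache)
      if (is.null(draw)) break
      g2 <- tryCatch(molmorph:::apply_graph_op(g, draw$op, draw$site),
                     error = function(e) NULL)
      if (!is.null(g2)) g <- g2
    }
    if (length(g$elem) <= max_atoms) graphs[[length(graphs) + 1L]] <- g
  }
  cans <- molmorph:::graphs_to_cansmi(graphs)
  mapply(function(g, cn) molmorph:::new_mol_record(g, cn),
         graphs, unname(cans), SIMPLIFY = FALSE)
}

# build a mol_fp with an explicit set of 1-based bit positions
fp_from_bits <- function(bits, nbits = 64L, kind = "TEST") {
  stopifnot(all(bits >= 1L), all(bits <= nbits), nbits %% 8L == 0L)
  lg <- rep(FALSE, nbits)
  lg[bits] <- TRUE
  molmorph:::new_fingerprint(packBits(lg, "raw"), kind, as.integer(nbits))
}

# naive popcount oracles on explicit logical vectors
naive_sim <- function(a_bits, b_bits, nbits, coeff) {
  a <- rep(FALSE, nbits); a[a_bits] <- TRUE
  b <- rep(FALSE, nbits); b[b_bits] <- TRUE
  ab <- sum(a & b); pa <- sum(a); pb <- sum(b)
  switch(coeff,
    TANIMOTO = if (pa + pb - ab == 0) 1 else ab / (pa + pb - ab),
    DICE = if (pa + pb == 0) 1 else 2 * ab / (pa + pb),
    COSINE = if (pa == 0 && pb == 0) 1 else if (pa == 0 || pb == 0) 0
             else ab / sqrt(pa * pb)
  )
}

# desk-scale search configuration used in search-heavy tests (see the
# methods vignette for the sizing rationale)
scaled_config <- function(seed = 1L, max_iterations = 50L) {
  exploration_config(n_gen_per_parent = 30L, accept_best = 15L,
                     accept_cap = 30L, idle_threshold = 3L, seed = seed,
                     max_iterations = max_iterations)
}
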