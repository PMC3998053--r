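test_that("job initialization sets up the tree contract", {
  job <- init_job("CCO", "CCN", exploration_config(seed = 1))
  expect_length(job$nodes, 1)
  expect_identical(job$iteration, 0L)
  expect_identical(job$status, "running")
  root <- job$nodes[[1]]
  expect_gt(root$dist, 0); expect_lte(root$dist, 1)

  # identical pair: already complete, zero iterations
  res <- run_exploration("CCO", "OCC", exploration_config(seed = 1))
  expect_true(res$complete)
  expect_identical(res$iterations_used, 0L)
  expect_length(res$path$molecules, 1)
  expect_length(res$path$operators, 0)
})

test_that("candidate selection is top-K plus rank-decayed acceptance", {
  scored <- data.frame(canonical = c("a", "b", "c"),
                       dist = c(0.5, 0.1, 0.3))
  cfg <- exploration_config(accept_best = 2, accept_cap = 2, seed = 1)
  sel <- select_candidates(scored, cfg)
  expect_identical(sel$canonical, c("b", "c"))
  expect_identical(sel$dist, c(0.1, 0.3))

  # infinite decay reduces to deterministic top-K
  cfg_inf <- exploration_config(accept_best = 3, accept_cap = 10,
                                decay = Inf, seed = 1)
  big <- data.frame(canonical = letters[1:10], dist = (1:10) / 10)
  withr::local_seed(4)
  for (i in 1:20) {
    expect_identical(select_candidates(big, cfg_inf)$canonical,
                     c("a", "b", "c"))
  }

  # empty input passes through
  expect_identical(NROW(select_candidates(big[0, ], cfg)), 0L)
})

test_that("rank K+1 acceptance frequency matches exp(-lambda/K)", {
  k <- 4L
  cfg <- exploration_config(accept_best = k, accept_cap = 10,
                            decay = 1, seed = 1)
  scored <- data.frame(canonical = letters[1:5], dist = (1:5) / 10)
  withr::local_seed(99)
  n_trials <- 10000L
  hits <- 0L
  for (i in seq_len(n_trials)) {
    hits <- hits + (nrow(select_candidates(scored, cfg)) == 5L)
  }
  p <- exp(-1 / k)
  se <- sqrt(p * (1 - p) / n_trials)
  expect_lt(abs(hits / n_trials - p), 3 * se + 1e-9)
})

test_that("iteration counting, death and reproducibility hold", {
  # methane under RA only: no applicable operator anywhere
  cfg <- exploration_config(enabled_ops = "RA", seed = 2)
  job <- init_job("C", "CC", cfg)
  job <- iterate(job)
  expect_identical(job$iteration, 1L)
  expect_identical(job$status, "dead")
  expect_error(iterate(job), "not running")

  # fixed seed, fixed config: identical trees
  p <- make_synthetic_pair("CC(=O)Oc1ccccc1C(=O)O", k = 2, seed = 77)
  cfg <- scaled_config(seed = 5, max_iterations = 20)
  r1 <- run_exploration(p$start, p$target, cfg)
  r2 <- run_exploration(p$start, p$target, cfg)
  expect_identical(r1$iterations_used, r2$iterations_used)
  expect_identical(names(r1$tree$nodes), names(r2$tree$nodes))
  expect_identical(r1$tree$log, r2$tree$log)

  # tree uniqueness: no canonical form twice, tabu disjoint from tree
  expect_false(anyDuplicated(names(r1$tree$nodes)) > 0)
  expect_length(intersect(r1$tree$tabu, names(r1$tree$nodes)), 0)
})

test_that("a target one obvious edit away is found immediately", {
  cfg <- exploration_config(enabled_ops = "AA", palette = "C",
                            n_gen_per_parent = 60, seed = 3)
  res <- run_exploration("CCCC", "CCCCC", cfg)
  expect_true(res$complete)
  expect_identical(res$iterations_used, 1L)
  expect_true(isTRUE(validate_path(res$path)))
})

test_that("pruning discards idle lineages but protects the best lineage", {
  cfg <- exploration_config(idle_threshold = 5, seed = 1)
  job <- init_job("CCCCCC", "CCCCCO", cfg)
  mk_node <- function(canon, parent, dist, idle) {
    list(canon = canon, parent = parent, op = "AA", site = "AA:atom1+C",
         site_obj = list(atom = 1L, elem = "C"), dist = dist, born = 1L,
         idle = idle, graph = canonicalize(canon)$graph)
  }
  root <- job$start$canonical_form
  job$nodes[["CCCCC"]] <- mk_node("CCCCC", root, 0.9, 5L)      # idle branch
  job$nodes[["CCCC"]] <- mk_node("CCCC", "CCCCC", 0.8, 0L)     # its child
  job$nodes[["CCCCCCC"]] <- mk_node("CCCCCCC", root, 0.2, 99L) # best node
  job$best <- "CCCCCCC"
  out <- prune(job)
  # the idle node goes together with its subtree
  expect_setequal(out$removed, c("CCCCC", "CCCC"))
  expect_true(all(out$removed %in% out$job$tabu))
  # best node survives arbitrary idleness; root always survives
  expect_true("CCCCCCC" %in% names(out$job$nodes))
  expect_true(root %in% names(out$job$nodes))
})

test_that("extracted paths follow parent links in order", {
  # two-edit chain search: S -> A -> B under atom additions only
  cfg <- exploration_config(enabled_ops = "AA", palette = "C",
                            n_gen_per_parent = 60, seed = 8,
                            max_iterations = 10)
  res <- run_exploration("CCCC", "CCCCCC", cfg)
  expect_true(res$complete)
  path <- res$path
  expect_length(path$molecules, 3)
  expect_identical(length(path$molecules), length(path$operators) + 1L)
  expect_identical(path$molecules[[1]]$canonical_form,
                   canonicalize("CCCC")$canonical_form)
  expect_identical(path$molecules[[3]]$canonical_form,
                   canonicalize("CCCCCC")$canonical_form)
  expect_true(isTRUE(validate_path(path)))

  # a mutation pair found through the full operator set
  p <- make_synthetic_pair("CCCCO", k = 2, seed = 19,
                           enabled = c("AA", "RA", "MA"),
                           palette = c("C", "N", "O"))
  res2 <- run_exploration(p$start, p$target, scaled_config(seed = 21))
  expect_true(res2$complete)
  expect_true(isTRUE(validate_path(res2$path)))

  # path to the root is a single molecule
  root_path <- extract_path(res$tree, canonicalize("CCCC")$canonical_form)
  expect_length(root_path$molecules, 1)
  expect_length(root_path$operators, 0)
  expect_error(extract_path(res$tree, "not-a-molecule"), "not in tree")
})

test_that("neighbourhood generation is exhaustive, bounded and radius-true", {
  expect_identical(NROW(generate_neighbourhood("C", max_depth = 0)), 0L)
  nb <- generate_neighbourhood("C", max_size = 10, max_radius = 1,
                               max_depth = 1, enabled = "AA", palette = "C")
  expect_identical(nb$canonical, "CC")
  expect_identical(nb$depth, 1L)

  nb2 <- generate_neighbourhood("CCO", max_size = 25, max_radius = 0.5,
                                max_depth = 2, palette = c("C", "N"))
  expect_lte(nrow(nb2), 25)
  expect_true(all(nb2$dist <= 0.5))
  expect_true(all(nb2$depth <= 2))
  expect_false(canonicalize("CCO")$canonical_form %in% nb2$canonical)
  # deterministic
  nb3 <- generate_neighbourhood("CCO", max_size = 25, max_radius = 0.5,
                                max_depth = 2, palette = c("C", "N"))
  expect_identical(nb2, nb3)
})
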