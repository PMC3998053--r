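test_that("SDF writing and reading round-trips molecules in order", {
  mols <- lapply(c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"), canonicalize)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, f)
  back <- read_sdf(f)
  expect_identical(vapply(back, `[[`, "", "canonical_form"),
                   vapply(mols, `[[`, "", "canonical_form"))
  # labels survive the round trip
  mols[[1]]$label <- "ethanol"
  write_sdf(mols, f)
  expect_identical(read_sdf(f)[[1]]$label, "ethanol")
})

test_that("a hand-written V2000 ethanol record parses to CCO", {
  block <- c(
    "ethanol", "  handmade", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$"
  )
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(block, f)
  out <- read_sdf(f)
  expect_length(out, 1)
  expect_identical(out[[1]]$canonical_form, "CCO")
  expect_identical(out[[1]]$label, "ethanol")
})

test_that("malformed SDF records fail fast or are skipped leniently", {
  good <- lapply(c("CCO", "CCN", "CCC"), canonicalize)
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(good, f)
  lines <- readLines(f)
  # corrupt the middle record's counts line
  idx <- grep("V2000", lines)[2]
  lines[idx] <- "  X  Y  0  0  0  0  0  0  0  0999 V2000"
  writeLines(lines, f)
  expect_error(read_sdf(f), "record 2")
  expect_message(out <- read_sdf(f, lenient = TRUE), "skipping")
  expect_length(out, 2)
  expect_error(read_sdf("does-not-exist.sdf"), "no such file")
})

test_that("pair files follow the odd-start/even-target dialect", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CCO 1001", "CCN 1002", "c1ccccc1 2001", "c1ccncc1 2002"), f)
  ps <- read_pairs(f)
  expect_length(ps$pairs, 2)
  expect_identical(ps$pairs[[1]]$start$canonical_form, "CCO")
  expect_identical(ps$pairs[[1]]$target$label, "1002")
  expect_identical(ps$pairs[[2]]$id, "2001/2002")

  writeLines(c("CCO 1", "CCN 2", "CCC 3"), f)
  expect_error(read_pairs(f), "odd number")
})

test_that("the per-pair statistic follows the protocol rules", {
  expect_equal(bench_pair_stat(c(3, 5, 1000, 4, 6),
                               c(TRUE, TRUE, FALSE, TRUE, TRUE)), 4.5)
  expect_equal(bench_pair_stat(rep(1000, 5), rep(FALSE, 5)), 1000)
  expect_equal(stats::median(c(3, 5, 7)), 5)
})

test_that("benchmark runs are reproducible and correctly aggregated", {
  pairs <- list(
    make_synthetic_pair("CCCCO", k = 1, enabled = "AA", palette = "C",
                        seed = 2),
    make_synthetic_pair("CCCN", k = 1, enabled = "AA", palette = "C",
                        seed = 4)
  )
  cfg <- exploration_config(enabled_ops = "AA", n_gen_per_parent = 60,
                            seed = 1)
  rep1 <- run_benchmark(pairs, cfg, reps = 2, cap = 10, base_seed = 7)
  rep2 <- run_benchmark(pairs, cfg, reps = 2, cap = 10, base_seed = 7)
  expect_identical(rep1$per_pair, rep2$per_pair)
  expect_identical(nrow(rep1$per_pair), 2L)
  runs <- as.matrix(rep1$per_pair[, c("run1", "run2")])
  expect_true(all(runs >= 1 & runs <= 10))
  expect_equal(rep1$dataset_median, median(rep1$per_pair$mean_success))
})

test_that("synthetic pairs carry a replayable trace", {
  expect_error(make_synthetic_pair("CCO", k = 0), "k >= 1")
  p <- make_synthetic_pair("CC(=O)Oc1ccccc1C(=O)O", k = 3, seed = 6)
  expect_length(p$operators, 3)
  expect_identical(replay_trace(p), p$target$canonical_form)
  expect_gte(p$similarity, 0); expect_lte(p$similarity, 1)
  expect_false(p$start$canonical_form == p$target$canonical_form)

  b <- make_band_pair("CN(C)CCCN1c2ccccc2CCc2ccccc12", c(0.5, 0.6),
                      seed = 12)
  expect_gte(b$similarity, 0.5); expect_lte(b$similarity, 0.6)
  expect_identical(replay_trace(b), b$target$canonical_form)
})

test_that("job files parse with defaults and reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(start = "CCO", target = "CCN", mw_limit = 400, seed = 9,
         operators = c("AA", "RA", "MA"), bogus_key = 1),
    f, auto_unbox = TRUE
  )
  expect_warning(job <- read_job(f), "bogus_key")
  expect_identical(job$start, "CCO")
  expect_equal(job$cfg$filters$mw_limit, 400)
  expect_identical(job$cfg$seed, 9L)
  expect_identical(job$cfg$enabled_ops, c("AA", "RA", "MA"))
  expect_error(read_job("missing.json"), "no such file")
})

test_that("the command line interface runs jobs and signals usage errors", {
  out_dir <- withr::local_tempdir()
  # degenerate run: start equals target
  status <- cli(c("run", "--start", "CCO", "--target", "OCC",
                  "--out", out_dir))
  expect_identical(status, 0L)
  expect_length(read_sdf(file.path(out_dir, "path.sdf")), 1)
  expect_true(file.exists(file.path(out_dir, "tree.tsv")))

  expect_identical(suppressMessages(cli(c("run", "--job", "nope.json"))), 2L)
  expect_identical(suppressMessages(cli(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(cli(c("run", "--start", "CCO"))), 2L)

  # benchmark subcommand on a tiny synthetic pair file
  pf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CCCC 1", "CCCCC 2", "CCCO 3", "CCCCO 4"), pf)
  bdir <- withr::local_tempdir()
  status <- cli(c("benchmark", "--pairs", pf, "--reps", "1",
                  "--operators", "AA", "--max-iterations", "5",
                  "--seed", "3", "--out", bdir))
  expect_identical(status, 0L)
  tab <- utils::read.delim(file.path(bdir, "benchmark.tsv"))
  expect_identical(nrow(tab), 2L)

  # neighbourhood and layout subcommands
  nfile <- file.path(out_dir, "nb.sdf")
  status <- cli(c("neighbourhood", "--origin", "C", "--max-depth", "1",
                  "--operators", "AA", "--out", nfile))
  expect_identical(status, 0L)
  expect_identical(read_sdf(nfile)[[1]]$canonical_form, "CC")

  rdir <- withr::local_tempdir()
  status <- cli(c("run", "--start", "CCCC", "--target", "CCCCC",
                  "--operators", "AA", "--seed", "3", "--out", rdir))
  expect_identical(status, 0L)
  lfile <- file.path(rdir, "coords.tsv")
  status <- cli(c("layout", "--tree", file.path(rdir, "tree.tsv"),
                  "--method", "pca", "--out", lfile))
  expect_identical(status, 0L)
  coords <- utils::read.delim(lfile)
  expect_gte(nrow(coords), 2L)
})
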