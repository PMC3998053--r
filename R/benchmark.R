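# Benchmark harness and the synthetic start/target pair generator.

# admissibility of a generator step: the molecule must keep at least three
# heavy atoms and pass the admission filters the search itself applies
pair_step_admissible <- function(g, filters, sa) {
  if (mg_natoms(g) < 3L) return(FALSE)
  if (mg_weight(g) > filters$mw_limit) return(FALSE)
  if (filters$sa_enabled) {
    fp <- fingerprint_batch(list(g), "MORGAN")[[1L]]
    if (sa_score_from_fp(fp$bits, g, sa) > filters$sa_threshold) return(FALSE)
  }
  TRUE
}

#' Build a synthetic start/target pair a known number of edits apart
#'
#' Applies `k` random valid operator applications to a seed molecule; the
#' final product becomes the target. Each step must change the canonical
#' form, so the pair is separated by at most `k` real edits. The operator
#' trace is returned so it can be replayed, together with the start/target
#' fingerprint similarity used to bin pairs into similarity bands.
#'
#' @param seed_mol Start molecule (SMILES or `mol_record`).
#' @param k Number of operator applications (>= 1).
#' @param enabled Operator codes.
#' @param palette Element palette; `NULL` derives it from the seed.
#' @param seed Optional RNG seed.
#' @param max_retries Random-trace restarts before giving up on a dead end.
#' @param fp_kind,coeff Fingerprint/coefficient for the reported similarity.
#' @param filters A [filter_config()] every intermediate and the target
#'   must pass. Benchmark pairs stand in for real, synthesizable
#'   compounds, and a target that fails the search's own admission
#'   filters would be unreachable by construction; the default mirrors
#'   the search defaults. Targets are additionally required to keep at
#'   least three heavy atoms.
#' @return List of class `synthetic_pair`: `start`, `target`
#'   (`mol_record`), `operators`, `sites`, `similarity`, `k`.
#' @export
make_synthetic_pair <- function(seed_mol, k, enabled = operator_kinds(),
                                palette = NULL, seed = NULL,
                                max_retries = 20L,
                                fp_kind = "MORGAN", coeff = "TANIMOTO",
                                filters = filter_config()) {
  stopifnot(k >= 1L)
  start <- canonicalize(seed_mol)
  enabled <- check_ops(enabled)
  if (is.null(palette)) palette <- default_palette(start)
  if (!is.null(seed)) local_seed(seed)
  sa <- sa_model()
  for (attempt in seq_len(max_retries)) {
    g <- start$graph
    prev_canon <- start$canonical_form
    ops <- character(0); sites <- list()
    ok <- TRUE
    for (step in seq_len(k)) {
      success <- FALSE
      for (draw_try in 1:10) {
        cache <- new.env(parent = emptyenv())
        draw <- draw_graph_morph(g, enabled, palette, cache)
        if (is.null(draw)) break
        g2 <- tryCatch(apply_graph_op(g, draw$op, draw$site),
                       error = function(e) NULL)
        if (is.null(g2)) next
        if (!pair_step_admissible(g2, filters, sa)) next
        canon <- unname(graphs_to_cansmi(list(g2), "m")[["m"]])
        if (is.null(canon) || !nzchar(canon) || canon == prev_canon) next
        g <- g2; prev_canon <- canon
        ops <- c(ops, draw$op)
        sites[[length(sites) + 1L]] <- draw$site
        success <- TRUE
        break
      }
      if (!success) { ok <- FALSE; break }
    }
    if (ok && prev_canon != start$canonical_form) {
      target <- record_from_graph(g, canonical_form = prev_canon)
      fps <- fingerprint_batch(list(start$graph, g), fp_kind)
      sim <- similarity(fps[[1L]], fps[[2L]], coeff)
      return(structure(list(start = start, target = target,
                            operators = ops, sites = sites,
                            similarity = sim, k = k),
                       class = "synthetic_pair"))
    }
  }
  stop("could not build a ", k, "-edit pair from ",
       start$canonical_form, " after ", max_retries, " attempts",
       call. = FALSE)
}

#' Build a synthetic pair within a start/target similarity band
#'
#' Extends a random edit trace from the seed molecule one operator at a
#' time until the start/target fingerprint similarity falls inside `band`.
#' The trace is constrained to a structural continuum: any single edit may
#' lower the similarity to the start by at most `max_step`, and edits that
#' would overshoot below the band are rejected. Low-similarity pairs are
#' therefore genuinely many gradual edits apart, emulating benchmark
#' datasets stratified at 70-80%, 50-60% and 30-40% similarity.
#'
#' @param seed_mol Start molecule.
#' @param band Numeric length-2: inclusive similarity bounds, e.g.
#'   `c(0.7, 0.8)`.
#' @param enabled,palette,seed,fp_kind,coeff As in [make_synthetic_pair()].
#' @param max_step Maximum similarity drop a single edit may cause.
#' @param max_edits Maximum trace length before restarting.
#' @param max_retries Trace restarts before giving up.
#' @param filters Admission filters every step must pass, as in
#'   [make_synthetic_pair()].
#' @return A `synthetic_pair` whose `similarity` lies in `band`.
#' @export
make_band_pair <- function(seed_mol, band, enabled = operator_kinds(),
                           palette = NULL, seed = NULL, max_step = 0.25,
                           max_edits = 40L, max_retries = 60L,
                           fp_kind = "MORGAN", coeff = "TANIMOTO",
                           filters = filter_config()) {
  stopifnot(length(band) == 2L, band[1L] < band[2L], max_step > 0)
  start <- canonicalize(seed_mol)
  if (is.null(palette)) palette <- default_palette(start)
  enabled <- check_ops(enabled)
  if (!is.null(seed)) local_seed(seed)
  sa <- sa_model()
  start_fp <- fingerprint_batch(list(start$graph), fp_kind)[[1L]]
  for (attempt in seq_len(max_retries)) {
    g <- start$graph
    prev_canon <- start$canonical_form
    prev_sim <- 1
    ops <- character(0); sites <- list()
    for (step in seq_len(max_edits)) {
      # evaluate a batch of candidate edits at once, then pick one at
      # random among those that respect the continuum constraints
      draws <- morph_graphs(g, 30L, enabled, palette)
      moved <- FALSE
      if (length(draws)) {
        graphs <- lapply(draws, `[[`, "graph")
        cans <- unname(graphs_to_cansmi(graphs))
        fps <- fingerprint_batch(graphs, fp_kind)
        sims <- vapply(fps, function(fp)
          similarity(start_fp, fp, coeff), 0)
        sa_fps <- if (toupper(fp_kind) == "MORGAN") fps
                  else fingerprint_batch(graphs, "MORGAN")
        admissible <- vapply(seq_along(graphs), function(i) {
          g2 <- graphs[[i]]
          mg_natoms(g2) >= 3L && mg_weight(g2) <= filters$mw_limit &&
            (!filters$sa_enabled ||
               sa_score_from_fp(sa_fps[[i]]$bits, g2, sa) <=
                 filters$sa_threshold)
        }, TRUE)
        ok <- which(admissible & cans != prev_canon & sims >= band[1L] &
                      prev_sim - sims <= max_step)
        if (length(ok)) {
          pick <- ok[[sample.int(length(ok), 1L)]]
          g <- graphs[[pick]]
          prev_canon <- cans[[pick]]
          prev_sim <- sims[[pick]]
          ops <- c(ops, draws[[pick]]$op)
          sites[[length(sites) + 1L]] <- draws[[pick]]$site
          moved <- TRUE
        }
      }
      if (!moved) break
      if (prev_sim <= band[2L] && prev_canon != start$canonical_form) {
        target <- record_from_graph(g, canonical_form = prev_canon)
        return(structure(list(start = start, target = target,
                              operators = ops, sites = sites,
                              similarity = prev_sim, k = length(ops)),
                         class = "synthetic_pair"))
      }
    }
  }
  stop("could not reach similarity band [", band[1L], ", ", band[2L],
       "] from ", start$canonical_form, call. = FALSE)
}

#' Replay a synthetic pair's operator trace
#'
#' @param pair A `synthetic_pair`.
#' @return Canonical form reached by applying the recorded trace to the
#'   start molecule (equals `pair$target$canonical_form`).
#' @export
replay_trace <- function(pair) {
  stopifnot(inherits(pair, "synthetic_pair"))
  g <- pair$start$graph
  for (i in seq_along(pair$operators)) {
    g <- apply_graph_op(g, pair$operators[[i]], pair$sites[[i]])
  }
  unname(graphs_to_cansmi(list(g), "m")[["m"]])
}

#' Per-pair benchmark statistic
#'
#' The headline per-pair statistic of the benchmark protocol: the mean
#' iteration count over successful runs, or `cap` when no run succeeded.
#'
#' @param iters Integer vector of per-run iteration counts (failed runs
#'   recorded as `cap`).
#' @param successes Logical vector marking which runs found the path.
#' @param cap The iteration cap.
#' @return A single number.
#' @export
bench_pair_stat <- function(iters, successes, cap = 1000L) {
  stopifnot(length(iters) == length(successes))
  if (any(successes)) mean(iters[successes]) else as.numeric(cap)
}

#' Run the benchmark protocol over a set of start/target pairs
#'
#' Each pair is explored `reps` times with seeds `base_seed + 1000 * p + r`
#' (pair index `p`, repetition `r`), capped at `cap` iterations. A failed
#' run counts as `cap` iterations. The per-pair statistic is the mean
#' iteration count over successful runs, or `cap` when no run succeeded;
#' the dataset statistic is the median of the per-pair statistics. The mean
#' with failures counted at `cap` is reported alongside.
#'
#' @param pairs A `benchmark_pairs`, or a list of `synthetic_pair` /
#'   `list(start, target, id)` items.
#' @param cfg An [exploration_config()] applied to every run (its `seed`
#'   and `max_iterations` are overridden per run).
#' @param reps Runs per pair.
#' @param cap Iteration cap per run.
#' @param base_seed Base seed of the seeding scheme.
#' @param verbose Print one line per run.
#' @return Object of class `benchmark_report`: `per_pair` data frame
#'   (`id`, `successes`, `mean_success`, `mean_capped`, one column per
#'   run), `dataset_median`, `dataset_median_capped` and the configuration
#'   echo.
#' @export
run_benchmark <- function(pairs, cfg = exploration_config(), reps = 5L,
                          cap = 1000L, base_seed = 1L, verbose = FALSE) {
  if (inherits(pairs, "benchmark_pairs")) pairs <- pairs$pairs
  stopifnot(length(pairs) >= 1L)
  rows <- list()
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    id <- if (!is.null(pr$id)) pr$id else paste0("pair", p)
    iters <- integer(reps); succ <- logical(reps)
    for (r in seq_len(reps)) {
      run_cfg <- cfg
      run_cfg$seed <- as.integer(base_seed + 1000L * p + r)
      run_cfg$max_iterations <- as.integer(cap)
      res <- run_exploration(pr$start, pr$target, run_cfg)
      succ[r] <- res$complete
      iters[r] <- if (res$complete) res$iterations_used else cap
      if (verbose) {
        message(sprintf("pair %s run %d: %s in %d iterations", id, r,
                        if (succ[r]) "found" else "not found", iters[r]))
      }
    }
    rows[[p]] <- c(
      list(id = id, successes = sum(succ),
           mean_success = bench_pair_stat(iters, succ, cap),
           mean_capped = mean(iters)),
      stats::setNames(as.list(iters), paste0("run", seq_len(reps)))
    )
  }
  per_pair <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(
    per_pair = per_pair,
    dataset_median = stats::median(per_pair$mean_success),
    dataset_median_capped = stats::median(per_pair$mean_capped),
    reps = reps, cap = cap, base_seed = base_seed, config = cfg
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$per_pair), " pairs x ", x$reps,
      " runs (cap ", x$cap, " iterations)\n", sep = "")
  print(x$per_pair, row.names = FALSE)
  cat("dataset median (mean over successful runs): ",
      x$dataset_median, "\n", sep = "")
  invisible(x)
}
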