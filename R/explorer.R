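# The exploration engine: an iterative, fingerprint-guided stochastic
# search growing a tree of unique molecules from the start structure until
# the target's canonical form is produced.
#
# Generational flow: the candidate set M_i holds the morphs accepted in
# iteration i plus any earlier candidates that have not yet produced an
# accepted child. Childless candidates accumulate idle iterations and are
# discarded (with their subtree) once idle_threshold is reached, unless
# they lie on the lineage of the current best molecule. Pruned canonical
# forms enter a tabu set and are never re-admitted.

#' Exploration configuration
#'
#' @param fp_kind Fingerprint kind, see [fingerprint_kinds()].
#' @param coeff Similarity coefficient, see [similarity_coefficients()].
#' @param enabled_ops Morphing operator codes, see [operator_kinds()].
#' @param palette Element palette for new/mutated atoms; `NULL` derives it
#'   from the target via [default_palette()].
#' @param filters A [filter_config()].
#' @param decoys List of decoy molecules (SMILES or `mol_record`).
#' @param n_gen_per_parent Random morph draws per candidate parent.
#' @param accept_best Number of best-ranked morphs accepted unconditionally
#'   (K).
#' @param accept_cap Maximum accepted morphs per iteration.
#' @param decay Rank-decay rate lambda of the acceptance probability
#'   `exp(-lambda * (r - K) / K)` for sorted rank `r > K`.
#' @param idle_threshold Iterations without an accepted child before a
#'   candidate is discarded.
#' @param max_iterations Iteration cap; reaching it yields a partial path.
#' @param seed Integer seed making the whole exploration reproducible.
#' @return Object of class `exploration_config`.
#' @export
exploration_config <- function(fp_kind = "MORGAN", coeff = "TANIMOTO",
                               enabled_ops = operator_kinds(),
                               palette = NULL,
                               filters = filter_config(),
                               decoys = list(),
                               n_gen_per_parent = 80L,
                               accept_best = 50L,
                               accept_cap = 150L,
                               decay = 1.0,
                               idle_threshold = 5L,
                               max_iterations = 1000L,
                               seed = 1L) {
  stopifnot(accept_best <= accept_cap, max_iterations >= 1L,
            n_gen_per_parent >= 1L, decay >= 0, idle_threshold >= 1L)
  structure(list(
    fp_kind = toupper(fp_kind), coeff = toupper(coeff),
    enabled_ops = check_ops(enabled_ops), palette = palette,
    filters = filters, decoys = decoys,
    n_gen_per_parent = as.integer(n_gen_per_parent),
    accept_best = as.integer(accept_best),
    accept_cap = as.integer(accept_cap),
    decay = decay, idle_threshold = as.integer(idle_threshold),
    max_iterations = as.integer(max_iterations),
    seed = as.integer(seed)
  ), class = "exploration_config")
}

#' Initialize an exploration job
#'
#' @param start,target Start and target molecules (SMILES or `mol_record`).
#' @param cfg An [exploration_config()].
#' @return Object of class `exploration`: the tree rooted at the start
#'   molecule with the start as the only candidate, at iteration 0. When
#'   start and target are identical the job is returned already in
#'   `"found"` status with a single-molecule path.
#' @export
init_job <- function(start, target, cfg = exploration_config()) {
  start <- canonicalize(start)
  target <- canonicalize(target)
  if (is.null(cfg$palette)) cfg$palette <- default_palette(target)
  model <- distance_model(target, cfg$decoys, cfg$fp_kind, cfg$coeff)
  root_dist <- distance(start, model)
  job <- structure(list(
    start = start, target = target, cfg = cfg, model = model,
    nodes = stats::setNames(
      list(list(canon = start$canonical_form, parent = NA_character_,
                op = NA_character_, site = NA_character_,
                dist = root_dist, born = 0L, idle = 0L,
                graph = start$graph)),
      start$canonical_form
    ),
    candidates = start$canonical_form,
    best = start$canonical_form,
    iteration = 0L,
    site_cache = new.env(parent = emptyenv()),
    tabu = character(0),
    status = if (identical(start$canonical_form, target$canonical_form))
      "found" else "running",
    log = data.frame()
  ), class = "exploration")
  job
}

#' @export
print.exploration <- function(x, ...) {
  cat("<exploration> ", x$start$canonical_form, " -> ",
      x$target$canonical_form,
      "\n  iteration ", x$iteration, ", status ", x$status,
      ", ", length(x$nodes), " molecules, best distance ",
      signif(x$nodes[[x$best]]$dist, 4), "\n", sep = "")
  invisible(x)
}

#' Probabilistic candidate selection
#'
#' Sorts scored morphs by distance to the target (ties broken by canonical
#' form, so ordering is deterministic), accepts the best `accept_best`
#' unconditionally, then accepts each morph at sorted rank `r > K` with
#' probability `exp(-decay * (r - K) / K)`, stopping once `accept_cap`
#' morphs are accepted.
#'
#' @param scored Data frame with columns `canonical` and `dist`,
#'   deduplicated against the existing tree.
#' @param cfg An [exploration_config()].
#' @return The accepted rows of `scored` in sorted order.
#' @export
select_candidates <- function(scored, cfg = exploration_config()) {
  if (!NROW(scored)) return(scored)
  ord <- order(scored$dist, scored$canonical)
  scored <- scored[ord, , drop = FALSE]
  n <- nrow(scored)
  k <- cfg$accept_best
  take <- rep(FALSE, n)
  take[seq_len(min(k, n))] <- TRUE
  if (n > k) {
    r <- seq.int(k + 1L, n)
    p <- exp(-cfg$decay * (r - k) / k)
    take[r] <- stats::runif(length(r)) < p
  }
  idx <- which(take)
  if (length(idx) > cfg$accept_cap) idx <- idx[seq_len(cfg$accept_cap)]
  scored[idx, , drop = FALSE]
}

# walk parent links to the root; returns canonical forms excluding `canon`
ancestors_of <- function(nodes, canon) {
  out <- character(0)
  p <- nodes[[canon]]$parent
  while (!is.na(p)) {
    out <- c(out, p)
    p <- nodes[[p]]$parent
  }
  out
}

#' Run one exploration iteration
#'
#' Generates morphs from every candidate, filters them, scores them against
#' the target (and decoys), selects the next generation, attaches it to the
#' tree, updates idle counters and prunes discarded lineages.
#'
#' Uses the current RNG stream; seed once per run ([run_exploration()] does
#' this from `cfg$seed`).
#'
#' @param job An `exploration` from [init_job()].
#' @return The updated `exploration`; `job$status` is one of `"running"`,
#'   `"found"` (target located) or `"dead"` (search exhausted).
#' @export
iterate <- function(job) {
  stopifnot(inherits(job, "exploration"))
  if (job$status != "running") {
    stop("job is not running (status: ", job$status, ")", call. = FALSE)
  }
  cfg <- job$cfg
  parents <- job$candidates

  # 1. generate morphs from every candidate parent
  pool_graph <- list(); pool_parent <- character(0)
  pool_op <- character(0); pool_site <- list()
  for (p in parents) {
    sc <- get0(p, envir = job$site_cache)
    if (is.null(sc)) {
      sc <- new.env(parent = emptyenv())
      assign(p, sc, envir = job$site_cache)
    }
    raw <- morph_graphs(job$nodes[[p]]$graph, cfg$n_gen_per_parent,
                        cfg$enabled_ops, cfg$palette, cache = sc)
    if (length(raw)) {
      pool_graph <- c(pool_graph, lapply(raw, `[[`, "graph"))
      pool_parent <- c(pool_parent, rep(p, length(raw)))
      pool_op <- c(pool_op, vapply(raw, `[[`, "", "op"))
      pool_site <- c(pool_site, lapply(raw, `[[`, "site"))
    }
  }
  n_generated <- length(pool_graph)

  accepted <- character(0)
  n_filtered <- 0L
  if (n_generated) {
    # 2. canonicalize in one batch; dedup within pool and against tree/tabu
    cans <- unname(graphs_to_cansmi(pool_graph))
    keep <- !duplicated(cans) &
      !(cans %in% names(job$nodes)) & !(cans %in% job$tabu)
    idx <- which(keep)

    if (length(idx)) {
      # 3. molecular weight filter (graph arithmetic, no conversion)
      mw <- vapply(pool_graph[idx], mg_weight, 0)
      mw_ok <- mw <= cfg$filters$mw_limit
      idx <- idx[mw_ok]
    }

    dists <- NULL
    if (length(idx)) {
      # 4. fingerprints; the MORGAN batch doubles as SA-filter input
      fps <- fingerprint_batch(pool_graph[idx], cfg$fp_kind)
      if (cfg$filters$sa_enabled) {
        sa_fps <- if (cfg$fp_kind == "MORGAN") fps
                  else fingerprint_batch(pool_graph[idx], "MORGAN")
        model <- sa_model()
        sa <- mapply(function(fp, g) sa_score_from_fp(fp$bits, g, model),
                     sa_fps, pool_graph[idx])
        sa_ok <- sa <= cfg$filters$sa_threshold
        idx <- idx[sa_ok]
        fps <- fps[sa_ok]
      }
      if (length(idx)) dists <- distance_batch(fps, job$model)
    }
    n_filtered <- length(idx)

    if (length(idx)) {
      # 5. probabilistic selection on the sorted list
      scored <- data.frame(canonical = cans[idx], dist = dists,
                           pool_i = idx, stringsAsFactors = FALSE)
      sel <- select_candidates(scored, cfg)

      # 6. attach accepted morphs as tree nodes
      for (r in seq_len(nrow(sel))) {
        i <- sel$pool_i[r]
        job$nodes[[sel$canonical[r]]] <- list(
          canon = sel$canonical[r], parent = pool_parent[i],
          op = pool_op[i],
          site = format_site(pool_op[i], pool_site[[i]]),
          site_obj = pool_site[[i]],
          dist = sel$dist[r], born = job$iteration + 1L, idle = 0L,
          graph = pool_graph[[i]]
        )
      }
      accepted <- sel$canonical
    }
  }

  # 7. idle bookkeeping
  child_parent <- vapply(accepted, function(cn) job$nodes[[cn]]$parent, "")
  for (p in parents) {
    kids <- accepted[child_parent == p]
    if (!length(kids)) {
      job$nodes[[p]]$idle <- job$nodes[[p]]$idle + 1L
    } else {
      improving <- any(vapply(kids, function(k) job$nodes[[k]]$dist, 0) <
                         job$nodes[[p]]$dist)
      if (improving) {
        for (a in c(p, ancestors_of(job$nodes, p))) job$nodes[[a]]$idle <- 0L
      }
    }
  }

  # 8. best node, pruning, next candidate set
  all_dist <- vapply(job$nodes, `[[`, 0, "dist")
  job$best <- names(which.min(all_dist))  # ties: first inserted (oldest)
  pruned <- prune_step(job)
  job <- pruned$job

  retained <- setdiff(parents[!parents %in% child_parent], pruned$removed)
  retained <- retained[retained %in% names(job$nodes)]
  job$candidates <- c(setdiff(accepted, pruned$removed), retained)
  job$iteration <- job$iteration + 1L

  found <- job$target$canonical_form %in% accepted
  job$status <- if (found) "found"
                else if (!length(job$candidates) || n_generated == 0L) "dead"
                else "running"
  job$log <- rbind(job$log, data.frame(
    iteration = job$iteration, candidates = length(parents),
    generated = n_generated, filtered = n_filtered,
    accepted = length(accepted), pruned = length(pruned$removed),
    best_dist = job$nodes[[job$best]]$dist
  ))
  job
}

# discard idle lineages: every non-root node with idle >= threshold that is
# not the best node nor one of its ancestors is removed with its whole
# subtree; removed canonical forms become tabu
prune_step <- function(job) {
  thr <- job$cfg$idle_threshold
  protected <- c(job$start$canonical_form, job$best,
                 ancestors_of(job$nodes, job$best))
  idle <- vapply(job$nodes, `[[`, 0L, "idle")
  seeds <- setdiff(names(job$nodes)[idle >= thr], protected)
  if (!length(seeds)) return(list(job = job, removed = character(0)))
  parent_of <- vapply(job$nodes, function(n) n$parent, "")
  removed <- character(0)
  queue <- seeds
  while (length(queue)) {
    cn <- queue[[1L]]; queue <- queue[-1L]
    if (cn %in% removed) next
    removed <- c(removed, cn)
    queue <- c(queue, names(parent_of)[!is.na(parent_of) & parent_of == cn])
  }
  removed <- setdiff(removed, protected)
  job$nodes[removed] <- NULL
  job$tabu <- union(job$tabu, removed)
  rm(list = intersect(removed, ls(job$site_cache)), envir = job$site_cache)
  list(job = job, removed = removed)
}

#' Prune idle lineages
#'
#' Applies the discard rule outside [iterate()] (which already prunes every
#' iteration): removes each non-root node whose idle counter has reached
#' `idle_threshold`, together with its subtree, unless it is the current
#' best node or one of its ancestors. Removed molecules enter the tabu set.
#'
#' @param job An `exploration`.
#' @return List with the updated `job` and `removed` canonical forms.
#' @export
prune <- function(job) {
  stopifnot(inherits(job, "exploration"))
  out <- prune_step(job)
  out$job$candidates <- setdiff(out$job$candidates, out$removed)
  out
}

#' Run a full exploration
#'
#' Seeds the random stream from `cfg$seed`, then iterates until the target
#' is found, the search dies out, or `max_iterations` is reached. With a
#' fixed seed and configuration the outcome is bit-reproducible.
#'
#' @param start,target Molecules (SMILES or `mol_record`).
#' @param cfg An [exploration_config()].
#' @param verbose Print one log line per iteration.
#' @return List with `path` (a `morphing_path`), `iterations_used`,
#'   `complete` (logical) and `tree` (the final `exploration` object).
#' @export
run_exploration <- function(start, target, cfg = exploration_config(),
                            verbose = FALSE) {
  local_seed(cfg$seed)
  job <- init_job(start, target, cfg)
  while (job$status == "running" && job$iteration < cfg$max_iterations) {
    job <- iterate(job)
    if (verbose) {
      l <- job$log[nrow(job$log), ]
      message(sprintf(
        "iter %d: candidates %d, generated %d, filtered %d, accepted %d, pruned %d, best %.4f",
        l$iteration, l$candidates, l$generated, l$filtered, l$accepted,
        l$pruned, l$best_dist))
    }
  }
  complete <- job$status == "found"
  end <- if (complete) job$target$canonical_form else job$best
  list(path = extract_path(job, end), iterations_used = job$iteration,
       complete = complete, tree = job)
}

#' Extract the morphing path to a molecule
#'
#' Follows parent links from `end` back to the start molecule.
#'
#' @param job An `exploration`.
#' @param end Canonical form of a molecule in the tree.
#' @return A `morphing_path`: `molecules` (list of `mol_record`, start
#'   first), `operators` and `sites` (one per step) and `complete` (end
#'   equals the target).
#' @export
extract_path <- function(job, end = job$best) {
  stopifnot(inherits(job, "exploration"))
  if (!end %in% names(job$nodes)) {
    stop("molecule not in tree: ", end, call. = FALSE)
  }
  chain <- c(end, ancestors_of(job$nodes, end))
  chain <- rev(chain)
  nodes <- job$nodes[chain]
  structure(list(
    molecules = lapply(nodes, function(n)
      record_from_graph(n$graph, canonical_form = n$canon)),
    operators = vapply(nodes[-1L], `[[`, "", "op"),
    sites = vapply(nodes[-1L], `[[`, "", "site"),
    sites_raw = lapply(nodes[-1L], `[[`, "site_obj"),
    complete = identical(end, job$target$canonical_form)
  ), class = "morphing_path")
}

#' Validate a morphing path step by step
#'
#' Replays every recorded operator application from the start molecule and
#' checks that each step reproduces the next molecule's canonical form.
#'
#' @param path A `morphing_path` from [extract_path()] or
#'   [run_exploration()].
#' @return `TRUE` if every step validates, otherwise `FALSE` (with the
#'   failing step index as attribute `"step"`).
#' @export
validate_path <- function(path) {
  stopifnot(inherits(path, "morphing_path"))
  n_steps <- length(path$operators)
  if (n_steps == 0L) return(TRUE)
  g <- path$molecules[[1L]]$graph
  for (i in seq_len(n_steps)) {
    g <- tryCatch(apply_graph_op(g, path$operators[[i]], path$sites_raw[[i]]),
                  error = function(e) NULL)
    if (is.null(g)) return(structure(FALSE, step = i))
    canon <- unname(graphs_to_cansmi(list(g), "m")[["m"]])
    if (!identical(canon, path$molecules[[i + 1L]]$canonical_form)) {
      return(structure(FALSE, step = i))
    }
  }
  TRUE
}

#' @export
print.morphing_path <- function(x, ...) {
  cat("<morphing_path> ", length(x$molecules), " molecules, ",
      length(x$operators), " operators, ",
      if (x$complete) "complete" else "partial", "\n", sep = "")
  forms <- vapply(x$molecules, `[[`, "", "canonical_form")
  steps <- c("", paste0(" [", x$operators, "] "))
  cat(paste0(steps, forms, collapse = "\n"), "\n")
  invisible(x)
}

#' Generate the near neighbourhood of a molecule
#'
#' Breadth-first exhaustive expansion from an origin molecule by morphing
#' operator applications. A molecule is kept if its operator depth is at
#' most `max_depth` and its fingerprint distance to the origin is at most
#' `max_radius`; expansion stops once `max_size` molecules are kept. The
#' origin itself is excluded. Deterministic: within each depth, molecules
#' are taken in lexicographic order of canonical form.
#'
#' @param origin Molecule (SMILES or `mol_record`).
#' @param max_size Maximum number of neighbours.
#' @param max_radius Maximum distance (1 - similarity) to the origin.
#' @param max_depth Maximum number of operator applications.
#' @param enabled Operator codes.
#' @param palette Element palette; `NULL` derives it from the origin.
#' @param fp_kind,coeff Fingerprint kind and similarity coefficient.
#' @return Data frame with columns `canonical`, `depth`, `dist`.
#' @export
generate_neighbourhood <- function(origin, max_size = 100L, max_radius = 1,
                                   max_depth = 2L,
                                   enabled = operator_kinds(),
                                   palette = NULL,
                                   fp_kind = "MORGAN", coeff = "TANIMOTO") {
  origin <- canonicalize(origin)
  stopifnot(max_size >= 1L, max_radius > 0, max_depth >= 0L)
  enabled <- check_ops(enabled)
  if (is.null(palette)) palette <- default_palette(origin)
  origin_fp <- fingerprint(origin, fp_kind)
  seen <- origin$canonical_form
  kept <- data.frame(canonical = character(0), depth = integer(0),
                     dist = numeric(0), stringsAsFactors = FALSE)
  frontier <- list(origin$graph)
  depth <- 0L
  while (depth < max_depth && length(frontier) && nrow(kept) < max_size) {
    depth <- depth + 1L
    prods <- list()
    for (g in frontier) {
      for (op in enabled) {
        for (site in sites_for_graph(g, op, palette)) {
          g2 <- tryCatch(apply_graph_op(g, op, site), error = function(e) NULL)
          if (!is.null(g2)) prods[[length(prods) + 1L]] <- g2
        }
      }
    }
    if (!length(prods)) break
    cans <- unname(graphs_to_cansmi(prods))
    first <- !duplicated(cans) & !(cans %in% seen)
    prods <- prods[first]; cans <- cans[first]
    ord <- order(cans)
    prods <- prods[ord]; cans <- cans[ord]
    seen <- c(seen, cans)
    if (!length(prods)) break
    fps <- fingerprint_batch(prods, fp_kind)
    d <- vapply(fps, function(fp) 1 - similarity(fp, origin_fp, coeff), 0)
    within <- d <= max_radius
    next_frontier <- list()
    for (i in which(within)) {
      if (nrow(kept) >= max_size) break
      kept <- rbind(kept, data.frame(canonical = cans[i], depth = depth,
                                     dist = d[i], stringsAsFactors = FALSE))
      next_frontier[[length(next_frontier) + 1L]] <- prods[[i]]
    }
    frontier <- next_frontier
  }
  kept
}
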