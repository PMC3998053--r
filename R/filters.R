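# Morph filtering: molecular weight cap and synthetic-accessibility score.
#
# The SA score follows the classical fragment-contribution-plus-complexity
# formulation: a molecule built from fragments that are common in known
# compounds and free of complexity features (large size, spiro/bridged
# rings, macrocycles) scores near 1 (easy to make); exotic fragments and
# complex ring systems push the score toward 10.
#
# The fragment-contribution table is not shipped verbatim: it is rebuilt at
# first use from a packaged plain-text reference library of common organic
# molecules (inst/extdata/synthetic_reference_library.smi, an authored
# stand-in set). Fragments are keyed by folded circular-fingerprint (ECFP4,
# 2048-bit) positions, and a fragment's contribution is the log10 document
# frequency of its bit in the library, centred on the 80th percentile and
# clipped to [-4, 4]; bits never seen in the library contribute -4.

#' Filter configuration
#'
#' @param mw_limit Maximum morph molecular weight in daltons (default 500).
#' @param sa_enabled Apply the synthetic-accessibility filter (default on).
#' @param sa_threshold Maximum tolerated SA score on the 1 (easy) to 10
#'   (hard) scale; default 6, the conventional hard-to-make boundary.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(mw_limit = 500, sa_enabled = TRUE,
                          sa_threshold = 6) {
  stopifnot(mw_limit > 0, sa_threshold >= 1, sa_threshold <= 10)
  structure(list(mw_limit = mw_limit, sa_enabled = isTRUE(sa_enabled),
                 sa_threshold = sa_threshold), class = "filter_config")
}

.sa_cache <- new.env(parent = emptyenv())

# raw-score scaling constants (calibrated once on the packaged library so
# its molecules span roughly 1-6 on the 1-10 scale)
.SA_RAW_MIN <- -4
.SA_RAW_MAX <- 1.5

#' Synthetic-accessibility model
#'
#' Builds (and caches) the fragment-contribution model from the packaged
#' reference library. Exposed mainly so alternative libraries can be
#' supplied.
#'
#' @param library_file Path to a two-column `SMILES name` text file;
#'   defaults to the packaged reference library.
#' @return Object of class `sa_model` with the per-bit contribution vector.
#' @export
sa_model <- function(library_file = NULL) {
  default <- is.null(library_file)
  if (default && !is.null(.sa_cache$model)) return(.sa_cache$model)
  if (default) {
    library_file <- system.file("extdata", "synthetic_reference_library.smi",
                                package = "molmorph", mustWork = TRUE)
  }
  lines <- readLines(library_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  smis <- vapply(strsplit(lines, "[ \t]+"), `[[`, "", 1L)
  spec <- fp_kind_spec("MORGAN")
  fps <- ob_fingerprints(smis, as.character(seq_along(smis)),
                         spec$ob_name, nbits = spec$fold, from = "smi")
  df <- integer(spec$nbits)
  for (r in fps) {
    bits <- which(as.logical(rawToBits(r)))
    df[bits] <- df[bits] + 1L
  }
  ref <- stats::quantile(df[df > 0], 0.8, names = FALSE)
  contrib <- ifelse(df > 0, pmin(pmax(log10(df) - log10(ref), -4), 4), -4)
  model <- structure(list(contrib = contrib, nbits = spec$nbits,
                          n_library = length(fps)), class = "sa_model")
  if (default) .sa_cache$model <- model
  model
}

# Bridge (non-ring) bonds by one iterative depth-first search (Tarjan
# low-link). Returns a logical vector over bond rows.
mg_bridges <- function(g) {
  n <- mg_natoms(g)
  m <- nrow(g$bond)
  if (!m) return(logical(0))
  # half-edge arrays: for each bond two directed entries
  head <- c(g$bond[, 2L], g$bond[, 1L])
  tail <- c(g$bond[, 1L], g$bond[, 2L])
  eid <- rep(seq_len(m), 2L)
  ord <- order(tail)
  head <- head[ord]; eid <- eid[ord]
  first <- match(seq_len(n), sort(tail))
  cnt <- tabulate(tail[order(tail)], n)
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  # explicit stack: (vertex, parent edge id, next half-edge offset)
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack_v <- root; stack_pe <- 0L; stack_i <- 0L
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack_v)) {
      top <- length(stack_v)
      v <- stack_v[top]
      i <- stack_i[top] + 1L
      if (i > cnt[v]) {
        # retreat
        pe <- stack_pe[top]
        stack_v <- stack_v[-top]; stack_pe <- stack_pe[-top]
        stack_i <- stack_i[-top]
        if (length(stack_v)) {
          u <- stack_v[length(stack_v)]
          if (low[v] < low[u]) low[u] <- low[v]
          if (low[v] > disc[u]) is_bridge[pe] <- TRUE
        }
        next
      }
      stack_i[top] <- i
      k <- first[v] + i - 1L
      w <- head[k]
      if (eid[k] == stack_pe[top]) next
      if (disc[w] == 0L) {
        timer <- timer + 1L
        disc[w] <- low[w] <- timer
        stack_v <- c(stack_v, w)
        stack_pe <- c(stack_pe, eid[k])
        stack_i <- c(stack_i, 0L)
      } else if (disc[w] < low[v]) {
        low[v] <- disc[w]
      }
    }
  }
  is_bridge
}

# TRUE if v is reachable from u within `cap` edges when one direct u-v
# edge is ignored (depth-capped BFS on a prebuilt adjacency list)
within_distance <- function(al, u, v, cap) {
  frontier <- setdiff(al[[u]], v)
  if (!length(frontier)) return(FALSE)
  seen <- c(u, frontier)
  for (depth in seq_len(cap - 1L)) {
    if (v %in% frontier) return(TRUE)
    frontier <- setdiff(unique(unlist(al[frontier])), seen)
    if (!length(frontier)) return(FALSE)
    seen <- c(seen, frontier)
  }
  v %in% frontier
}

# Ring-derived complexity features from the molecular graph. The result
# depends only on the topology of the ring-bond subgraph, so it is cached
# under the relabeled ring edge list (morphs editing side chains share the
# unchanged ring system).
.ring_cache <- new.env(parent = emptyenv())

ring_features <- function(g) {
  m <- nrow(g$bond)
  none <- list(macrocycle = FALSE, n_spiro = 0L, n_bridge = 0L)
  if (!m) return(none)
  ring <- !mg_bridges(g)
  if (!any(ring)) return(none)
  rb <- g$bond[ring, 1:2, drop = FALSE]
  ra <- sort(unique(as.vector(rb)))
  e1 <- match(rb[, 1L], ra); e2 <- match(rb[, 2L], ra)
  key <- paste(c(e1, e2), collapse = ",")
  hit <- .ring_cache[[key]]
  if (!is.null(hit)) return(hit)

  nr <- length(ra)
  # ring degree per (relabeled) ring atom
  rd <- tabulate(c(e1, e2), nr)
  # ring systems: connected components of the ring-bond subgraph
  comp <- seq_len(nr)
  repeat {
    changed <- FALSE
    for (r in seq_along(e1)) {
      ca <- comp[e1[r]]; cb <- comp[e2[r]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  macro <- FALSE
  al <- NULL
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    nbonds <- sum(comp[e1] == cid)
    cyc <- nbonds - length(members) + 1L
    if (cyc == 1L) {
      # plain ring: its size is the component size
      if (length(members) > 8L) macro <- TRUE
    } else if (length(members) > 12L) {
      # fused system large enough to hide a macrocycle: a ring bond whose
      # endpoints are farther than 7 steps apart without it closes a ring
      # of more than 8 atoms
      if (is.null(al)) al <- mg_adjacency_list(g)
      for (r in which(comp[e1] == cid)) {
        if (!within_distance(al, ra[e1[r]], ra[e2[r]], 7L)) {
          macro <- TRUE
          break
        }
      }
    }
  }
  out <- list(macrocycle = macro, n_spiro = sum(rd >= 4L),
              n_bridge = sum(rd == 3L))
  if (length(.ring_cache) > 50000L) {
    rm(list = ls(.ring_cache), envir = .ring_cache)
  }
  .ring_cache[[key]] <- out
  out
}

# raw SA score from a molecule's folded circular-fingerprint bits and graph
sa_raw <- function(bits, g, model) {
  frag <- if (length(bits)) mean(model$contrib[bits]) else -4
  n <- mg_natoms(g)
  size_pen <- n^1.005 - n
  rf <- ring_features(g)
  ring_pen <- log10(rf$n_spiro + 1) + log10(rf$n_bridge + 1) +
    if (rf$macrocycle) log10(2) else 0
  # symmetry bonus: fewer distinct environments than atoms means a regular,
  # easier structure
  sym <- if (n > length(bits) && length(bits) > 0) 0.5 * log(n / length(bits)) else 0
  frag - size_pen - ring_pen + sym
}

sa_scale <- function(raw) {
  s <- 11 - (raw - .SA_RAW_MIN + 1) / (.SA_RAW_MAX - .SA_RAW_MIN + 1) * 9
  if (s > 8) s <- 8 + log(s - 8 + 1)
  min(max(s, 1), 10)
}

#' Synthetic-accessibility score
#'
#' @param mol `mol_record` or SMILES string.
#' @param model An [sa_model()]; defaults to the packaged model.
#' @return Score in \[1, 10\]: 1 easy to synthesize, 10 hard.
#' @export
sa_score <- function(mol, model = sa_model()) {
  mol <- canonicalize(mol)
  fp <- fingerprint(mol, "MORGAN")
  sa_score_from_fp(fp$bits, mol$graph, model)
}

sa_score_from_fp <- function(raw_bits, g, model) {
  bits <- which(as.logical(rawToBits(raw_bits)))
  sa_scale(sa_raw(bits, g, model))
}

#' Apply the morph filters
#'
#' A morph survives iff its molecular weight is at most `cfg$mw_limit` and,
#' when the SA filter is enabled, its SA score is at most
#' `cfg$sa_threshold`. Order is preserved; rejection counts per filter are
#' returned alongside.
#'
#' @param morphs List of `morph_result` (or `mol_record`) objects.
#' @param cfg A [filter_config()].
#' @param model An [sa_model()].
#' @return List with `survivors` (same class as the input elements) and
#'   `rejections` (named counts: `mol_weight`, `sa_score`).
#' @export
apply_filters <- function(morphs, cfg = filter_config(), model = sa_model()) {
  stopifnot(inherits(cfg, "filter_config"))
  rej <- c(mol_weight = 0L, sa_score = 0L)
  if (!length(morphs)) {
    return(list(survivors = list(), rejections = rej))
  }
  recs <- lapply(morphs, function(m) {
    if (inherits(m, "morph_result")) m$product else canonicalize(m)
  })
  mw_ok <- vapply(recs, function(r) r$mol_weight <= cfg$mw_limit, TRUE)
  rej[["mol_weight"]] <- sum(!mw_ok)
  keep <- mw_ok
  if (cfg$sa_enabled && any(mw_ok)) {
    idx <- which(mw_ok)
    fps <- fingerprint_batch(lapply(recs[idx], `[[`, "graph"), "MORGAN")
    sa <- mapply(function(fp, r) sa_score_from_fp(fp$bits, r$graph, model),
                 fps, recs[idx])
    sa_ok <- sa <= cfg$sa_threshold
    rej[["sa_score"]] <- sum(!sa_ok)
    keep[idx[!sa_ok]] <- FALSE
  }
  list(survivors = morphs[keep], rejections = rej)
}
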