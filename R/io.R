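# Molecule file I/O and job configuration.

#' Read molecules from an SDF file
#'
#' Parses a V2000 SDF file via ChemmineR and converts every record to a
#' `mol_record`. Record titles become labels.
#'
#' @param path Path to the SDF file.
#' @param lenient Skip unreadable records with a message instead of
#'   failing; default is fail-fast with the record index in the error.
#' @return List of `mol_record`.
#' @export
read_sdf <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!length(readLines(path, n = 1L, warn = FALSE))) return(list())
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- list()
  for (i in seq_along(sdfset)) {
    rec <- tryCatch({
      block <- ChemmineR::sdf2str(sdfset[[i]])
      parsed <- parse_molblock(block)
      mg_validate(parsed$graph)
      cans <- unname(graphs_to_cansmi(list(parsed$graph), "m")[["m"]])
      if (is.null(cans) || !nzchar(cans)) stop("canonicalization failed")
      new_mol_record(parsed$graph, cans,
                     label = if (nzchar(parsed$id)) parsed$id else NULL)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      if (lenient) {
        message("skipping SDF record ", i, ": ", conditionMessage(rec))
      } else {
        stop("SDF record ", i, " in ", path, ": ", conditionMessage(rec),
             call. = FALSE)
      }
    } else {
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Write molecules to an SDF file
#'
#' @param mols List of `mol_record` (or SMILES strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  mols <- lapply(mols, canonicalize)
  ids <- vapply(seq_along(mols), function(i) {
    lb <- mols[[i]]$label
    if (!is.null(lb) && nzchar(lb)) lb else mols[[i]]$canonical_form
  }, "")
  writeLines(mg_sdf_batch(lapply(mols, `[[`, "graph"), ids), path)
  invisible(path)
}

#' Read a benchmark pair file
#'
#' Two-column text: each line holds a SMILES and an identifier; each odd
#' line is a start structure and the following line its target.
#'
#' @param path Path to the pair file.
#' @return Object of class `benchmark_pairs`: list of
#'   `list(start, target, id)` plus the source dialect tag.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 2L != 0L) {
    stop("pair file ", path, " has an odd number of lines (",
         length(lines), ")", call. = FALSE)
  }
  parts <- strsplit(lines, "[ \t]+")
  smis <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  pairs <- lapply(seq_len(length(lines) / 2L), function(k) {
    s <- canonicalize(smis[2L * k - 1L], label = ids[2L * k - 1L])
    t <- canonicalize(smis[2L * k], label = ids[2L * k])
    list(start = s, target = t,
         id = paste0(ids[2L * k - 1L], "/", ids[2L * k]))
  })
  structure(list(pairs = pairs, dialect = "smiles-id"),
            class = "benchmark_pairs")
}

#' Read a job configuration file
#'
#' Flat JSON key/value job description. Recognized keys: `start`, `target`,
#' `decoys`, `fingerprint`, `coefficient`, `operators`, `mw_limit`,
#' `sa_enabled`, `sa_threshold`, `n_gen_per_parent`, `accept_best`,
#' `accept_cap`, `decay`, `idle_threshold`, `max_iterations`, `seed`,
#' `out_dir`. Unknown keys are rejected with a warning.
#'
#' @param path Path to the JSON job file.
#' @return List with `start`, `target` (SMILES strings), `cfg`
#'   (an [exploration_config()]) and `out_dir`.
#' @export
read_job <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("start", "target", "decoys", "fingerprint", "coefficient",
             "operators", "mw_limit", "sa_enabled", "sa_threshold",
             "n_gen_per_parent", "accept_best", "accept_cap", "decay",
             "idle_threshold", "max_iterations", "seed", "out_dir")
  unknown <- setdiff(names(j), known)
  if (length(unknown)) {
    warning("ignoring unknown job key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  if (is.null(j$start) || is.null(j$target)) {
    stop("job file must define 'start' and 'target'", call. = FALSE)
  }
  pick <- function(key, default) if (is.null(j[[key]])) default else j[[key]]
  cfg <- exploration_config(
    fp_kind = pick("fingerprint", "MORGAN"),
    coeff = pick("coefficient", "TANIMOTO"),
    enabled_ops = pick("operators", operator_kinds()),
    filters = filter_config(
      mw_limit = pick("mw_limit", 500),
      sa_enabled = pick("sa_enabled", TRUE),
      sa_threshold = pick("sa_threshold", 6)
    ),
    decoys = as.list(pick("decoys", character(0))),
    n_gen_per_parent = pick("n_gen_per_parent", 80L),
    accept_best = pick("accept_best", 50L),
    accept_cap = pick("accept_cap", 150L),
    decay = pick("decay", 1.0),
    idle_threshold = pick("idle_threshold", 5L),
    max_iterations = pick("max_iterations", 1000L),
    seed = pick("seed", 1L)
  )
  list(start = j$start, target = j$target, cfg = cfg,
       out_dir = pick("out_dir", "."))
}

#' Export an exploration tree as a table
#'
#' @param job An `exploration`.
#' @param path Optional output path (tab-separated).
#' @return Data frame with one row per molecule: `canonical`, `parent`,
#'   `op`, `site`, `dist`, `born`, `idle`.
#' @export
tree_table <- function(job, path = NULL) {
  stopifnot(inherits(job, "exploration"))
  df <- data.frame(
    canonical = names(job$nodes),
    parent = vapply(job$nodes, function(n) n$parent, ""),
    op = vapply(job$nodes, function(n) n$op, ""),
    site = vapply(job$nodes, function(n) n$site, ""),
    dist = vapply(job$nodes, `[[`, 0, "dist"),
    born = vapply(job$nodes, `[[`, 0L, "born"),
    idle = vapply(job$nodes, `[[`, 0L, "idle"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
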