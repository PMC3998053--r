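# Molecule records, fingerprints, similarity coefficients and the
# target/decoy distance model.

new_mol_record <- function(graph, canonical_form, label = NULL) {
  structure(list(
    canonical_form = canonical_form,
    mol_weight = mg_weight(graph),
    element_multiset = as.list(table(graph$elem)),
    graph = graph,
    label = label
  ), class = "mol_record")
}

#' Canonicalize a molecule
#'
#' Parses a SMILES string (or an SDF molblock already turned into a record
#' by [read_sdf()]) into a `mol_record`: the package's molecule identity
#' unit. Two inputs denoting the same molecule yield the same
#' `canonical_form` (canonical SMILES), which is what the explorer uses for
#' deduplication and target detection.
#'
#' Scope: single-fragment, neutral organic molecules over the elements in
#' [element_table()]. Stereochemistry and isotopes are out of scope; explicit
#' hydrogens are stripped.
#'
#' @param structure A SMILES string, or a `mol_record` (returned unchanged).
#' @param label Optional external identifier carried along.
#' @return An object of class `mol_record` with fields `canonical_form`,
#'   `mol_weight` (Da, implicit hydrogens included), `element_multiset`,
#'   `graph` (internal graph handle) and `label`.
#' @examples
#' \dontrun{
#' canonicalize("OCC")$canonical_form == canonicalize("CCO")$canonical_form
#' }
#' @export
canonicalize <- function(structure, label = NULL) {
  if (inherits(structure, "mol_record")) return(structure)
  stopifnot(is.character(structure), length(structure) == 1L)
  smi <- trimws(structure)
  if (!nzchar(smi)) stop("empty structure string", call. = FALSE)
  if (grepl(".", smi, fixed = TRUE)) {
    stop("rejected input '", smi, "': disconnected (multi-fragment) structure",
         call. = FALSE)
  }
  g <- tryCatch(smiles_to_graphs(smi, "m")[["m"]],
                error = function(e) NULL)
  if (is.null(g)) {
    stop("rejected input '", smi, "': could not be parsed as a molecule",
         call. = FALSE)
  }
  ok <- mg_check(g)
  if (!isTRUE(ok)) {
    stop("rejected input '", smi, "': ", ok, call. = FALSE)
  }
  record_from_graph(g, label = label)
}

# canonical record straight from a validated molgraph (internal fast path)
record_from_graph <- function(g, canonical_form = NULL, label = NULL) {
  if (is.null(canonical_form)) {
    canonical_form <- unname(graphs_to_cansmi(list(g), "m")[["m"]])
    if (is.null(canonical_form) || !nzchar(canonical_form)) {
      stop("canonicalization failed for internal graph", call. = FALSE)
    }
  }
  new_mol_record(g, canonical_form, label)
}

#' @export
print.mol_record <- function(x, ...) {
  cat("<mol_record> ", x$canonical_form,
      sprintf("  (MW %.2f Da", x$mol_weight),
      if (!is.null(x$label)) paste0(", ", x$label) else "", ")\n", sep = "")
  invisible(x)
}

# ---- fingerprint kinds -------------------------------------------------

# Extensible registry: each kind maps to an obabel fingerprint name, an
# optional fold width and the resulting bit-vector length.
.fp_registry <- new.env(parent = emptyenv())

register_fp_kind <- function(kind, ob_name, nbits, fold = NULL) {
  assign(kind, list(kind = kind, ob_name = ob_name, nbits = nbits,
                    fold = fold), envir = .fp_registry)
}

# MORGAN: circular ECFP4-type (radius 2), folded to 2048 bits.
# PATH: linear paths up to 7 atoms (OpenBabel FP2), 1024 bits.
# MACCS_LIKE: 166 structural keys in a 256-bit block.
register_fp_kind("MORGAN", "ECFP4", 2048L, fold = 2048L)
register_fp_kind("PATH", "FP2", 1024L)
register_fp_kind("MACCS_LIKE", "MACCS", 256L)

#' Available fingerprint kinds
#' @return Data frame with columns `kind` and `nbits`.
#' @export
fingerprint_kinds <- function() {
  ks <- sort(ls(.fp_registry))
  data.frame(
    kind = ks,
    nbits = vapply(ks, function(k) get(k, envir = .fp_registry)$nbits, 0L),
    row.names = NULL
  )
}

fp_kind_spec <- function(kind) {
  kind <- toupper(kind)
  if (!exists(kind, envir = .fp_registry)) {
    stop("unknown fingerprint kind '", kind, "'; available: ",
         paste(sort(ls(.fp_registry)), collapse = ", "), call. = FALSE)
  }
  get(kind, envir = .fp_registry)
}

new_fingerprint <- function(bits, kind, nbits) {
  structure(list(bits = bits, length = nbits, kind = kind),
            class = "mol_fp")
}

#' Compute a molecular fingerprint
#'
#' @param mol A `mol_record` (or SMILES string).
#' @param kind One of the registered kinds, see [fingerprint_kinds()];
#'   default `"MORGAN"` (circular, radius-2 equivalent, 2048 bits).
#' @return Object of class `mol_fp`: packed bit vector (`bits`, raw),
#'   `length` (bit count) and `kind`.
#' @export
fingerprint <- function(mol, kind = "MORGAN") {
  mol <- canonicalize(mol)
  fingerprint_batch(list(mol$graph), kind)[[1L]]
}

# batch fingerprints for a list of molgraphs (internal hot path)
fingerprint_batch <- function(graphs, kind = "MORGAN") {
  spec <- fp_kind_spec(kind)
  ids <- as.character(seq_along(graphs))
  raws <- ob_fingerprints(mg_sdf_batch(graphs, ids), ids,
                          spec$ob_name, nbits = spec$fold, from = "sdf")
  if (length(raws) != length(graphs) ||
      !identical(sort(as.integer(names(raws))), seq_along(graphs))) {
    stop("fingerprint computation dropped molecules", call. = FALSE)
  }
  raws <- raws[ids]
  lapply(raws, new_fingerprint, kind = spec$kind, nbits = spec$nbits)
}

# ---- popcount / similarity ---------------------------------------------

.POP8 <- vapply(0:255, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:7)) > 0L), 0L)

popcount_raw <- function(r) sum(.POP8[as.integer(r) + 1L])

.coeff_registry <- new.env(parent = emptyenv())

register_coefficient <- function(name, fn) {
  assign(name, fn, envir = .coeff_registry)
}

# all coefficients: value for two all-zero vectors defined as 1 (identical)
register_coefficient("TANIMOTO", function(ab, pa, pb) {
  denom <- pa + pb - ab
  if (denom == 0) 1 else ab / denom
})
register_coefficient("DICE", function(ab, pa, pb) {
  if (pa + pb == 0) 1 else 2 * ab / (pa + pb)
})
register_coefficient("COSINE", function(ab, pa, pb) {
  if (pa == 0 && pb == 0) 1 else if (pa == 0 || pb == 0) 0
  else ab / sqrt(pa * pb)
})

#' Available similarity coefficients
#' @return Character vector of coefficient names.
#' @export
similarity_coefficients <- function() sort(ls(.coeff_registry))

coeff_fn <- function(coeff) {
  coeff <- toupper(coeff)
  if (!exists(coeff, envir = .coeff_registry)) {
    stop("unknown similarity coefficient '", coeff, "'; available: ",
         paste(similarity_coefficients(), collapse = ", "), call. = FALSE)
  }
  get(coeff, envir = .coeff_registry)
}

#' Fingerprint similarity
#'
#' Bit-vector similarity between two fingerprints of the same kind.
#' Tanimoto is `|a AND b| / |a OR b|`; Dice `2|a AND b|/(|a|+|b|)`; Cosine
#' `|a AND b| / sqrt(|a||b|)`. Two all-zero vectors compare as 1.
#'
#' @param a,b `mol_fp` objects of equal kind and length.
#' @param coeff `"TANIMOTO"` (default), `"DICE"` or `"COSINE"`.
#' @return Similarity in \[0, 1\].
#' @export
similarity <- function(a, b, coeff = "TANIMOTO") {
  stopifnot(inherits(a, "mol_fp"), inherits(b, "mol_fp"))
  if (a$length != b$length || !identical(a$kind, b$kind)) {
    stop("fingerprints differ in kind or length", call. = FALSE)
  }
  fn <- coeff_fn(coeff)
  ab <- popcount_raw(a$bits & b$bits)
  fn(ab, popcount_raw(a$bits), popcount_raw(b$bits))
}

# ---- distance model ----------------------------------------------------

#' Target/decoy distance model
#'
#' Packages the target fingerprint, optional decoy fingerprints and the
#' similarity coefficient into the scoring model used by the explorer.
#'
#' @param target `mol_record` of the target molecule.
#' @param decoys List of decoy `mol_record`s (may be empty). Decoys steer the
#'   search through remoter regions of chemical space.
#' @param fp_kind Fingerprint kind for all molecules in the model.
#' @param coeff Similarity coefficient name.
#' @return Object of class `distance_model`.
#' @export
distance_model <- function(target, decoys = list(), fp_kind = "MORGAN",
                           coeff = "TANIMOTO") {
  target <- canonicalize(target)
  decoys <- lapply(decoys, canonicalize)
  graphs <- c(list(target$graph), lapply(decoys, `[[`, "graph"))
  fps <- fingerprint_batch(graphs, fp_kind)
  structure(list(
    target_fp = fps[[1L]],
    decoy_fps = fps[-1L],
    coeff = toupper(coeff),
    fp_kind = toupper(fp_kind),
    target_canonical = target$canonical_form
  ), class = "distance_model")
}

#' Distance of a molecule to the exploration target
#'
#' Without decoys the distance is `1 - similarity(mol, target)`. With decoys
#' the distance to the nearest decoy is averaged in:
#' `(d_target + min_k d_decoy_k) / 2`, so a decoy can shift the distance by
#' at most 0.5.
#'
#' @param mol `mol_record`, `mol_fp`, or SMILES string.
#' @param model A [distance_model()].
#' @return Distance in \[0, 1\].
#' @export
distance <- function(mol, model) {
  stopifnot(inherits(model, "distance_model"))
  fp <- if (inherits(mol, "mol_fp")) mol
        else fingerprint(canonicalize(mol), model$fp_kind)
  d_t <- 1 - similarity(fp, model$target_fp, model$coeff)
  if (length(model$decoy_fps) == 0) return(d_t)
  d_dec <- vapply(model$decoy_fps,
                  function(d) 1 - similarity(fp, d, model$coeff), 0)
  (d_t + min(d_dec)) / 2
}

# vectorized internal scorer over a list of mol_fp
distance_batch <- function(fps, model) {
  vapply(fps, distance, 0, model = model)
}
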