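# Internal heavy-atom molecular graph.
#
# A `molgraph` is a plain list: `elem` -- character vector of element
# symbols; `bond` -- integer matrix with columns (i, j, order), i < j.
# Hydrogens are implicit (default valence minus bond-order sum), bonds are
# kekule orders 1..3. This is the structure the morphing operators edit.

mg_new <- function(elem, bond = NULL) {
  if (is.null(bond) || NROW(bond) == 0) {
    bond <- matrix(integer(0), ncol = 3L)
  } else {
    bond <- matrix(as.integer(bond), ncol = 3L)
    swap <- bond[, 1L] > bond[, 2L]
    if (any(swap)) bond[swap, 1:2] <- bond[swap, 2:1]
  }
  colnames(bond) <- c("i", "j", "order")
  structure(list(elem = as.character(elem), bond = bond), class = "molgraph")
}

mg_natoms <- function(g) length(g$elem)

# bond-order sum per atom
mg_valsum <- function(g) {
  if (!nrow(g$bond)) return(integer(mg_natoms(g)))
  ends <- c(g$bond[, 1L], g$bond[, 2L])
  tabulate(rep.int(ends, rep.int(g$bond[, 3L], 2L)), mg_natoms(g))
}

mg_degree <- function(g) {
  if (!nrow(g$bond)) return(integer(mg_natoms(g)))
  tabulate(c(g$bond[, 1L], g$bond[, 2L]), mg_natoms(g))
}

# free valence under the default-valence model (never negative; hypervalent
# input atoms simply have zero headroom)
mg_free_valence <- function(g) {
  pmax(element_default_valence(g$elem) - mg_valsum(g), 0L)
}

mg_adjacency_list <- function(g) {
  n <- mg_natoms(g)
  if (!nrow(g$bond)) return(vector("list", n))
  unname(split(c(g$bond[, 2L], g$bond[, 1L]),
               factor(c(g$bond[, 1L], g$bond[, 2L]), levels = seq_len(n))))
}

# connectivity by BFS; `drop_bond` (row index) excludes one bond, which is
# how ring membership of a bond is tested
mg_connected <- function(g, drop_bond = NULL) {
  n <- mg_natoms(g)
  if (n <= 1L) return(TRUE)
  b <- g$bond
  if (!is.null(drop_bond)) b <- b[-drop_bond, , drop = FALSE]
  if (nrow(b) < n - 1L) return(FALSE)
  adj <- mg_new(g$elem, b)
  al <- mg_adjacency_list(adj)
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    nb <- al[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# BFS component of `from`, with bond row `drop_bond` removed
mg_component_of <- function(g, from, drop_bond = NULL) {
  b <- g$bond
  if (!is.null(drop_bond)) b <- b[-drop_bond, , drop = FALSE]
  al <- mg_adjacency_list(mg_new(g$elem, b))
  seen <- logical(mg_natoms(g))
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    nb <- al[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  which(seen)
}

# TRUE per bond row if the bond lies in a ring (removal keeps the graph
# connected)
mg_ring_bonds <- function(g) {
  nb <- nrow(g$bond)
  if (!nb) return(logical(0))
  vapply(seq_len(nb), function(k) mg_connected(g, drop_bond = k), TRUE)
}

# smallest ring size through bond row k (Inf when k is not a ring bond):
# shortest path between the endpoints avoiding the bond, plus one
mg_ring_size <- function(g, k) {
  i <- g$bond[k, 1L]; j <- g$bond[k, 2L]
  b <- g$bond[-k, , drop = FALSE]
  al <- mg_adjacency_list(mg_new(g$elem, b))
  n <- mg_natoms(g)
  dist <- rep(NA_integer_, n)
  dist[i] <- 0L
  queue <- i
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur == j) break
    nb2 <- al[[cur]]
    new <- nb2[is.na(dist[nb2])]
    dist[new] <- dist[cur] + 1L
    queue <- c(queue, new)
  }
  if (is.na(dist[j])) Inf else dist[j] + 1L
}

# Validate valence, connectivity and non-emptiness. Returns TRUE or a
# character reason. `connectivity = FALSE` skips the BFS for callers that
# guarantee connectedness by construction.
mg_check <- function(g, connectivity = TRUE) {
  n <- mg_natoms(g)
  if (n == 0L) return("empty molecule")
  if (!all(g$elem %in% .ELEMENTS$symbol)) {
    return(paste0("unsupported element: ",
                  paste(setdiff(g$elem, .ELEMENTS$symbol), collapse = ",")))
  }
  if (nrow(g$bond)) {
    if (any(g$bond[, 3L] < 1L | g$bond[, 3L] > 3L)) return("bond order outside 1..3")
    if (any(g$bond[, 1:2] < 1L | g$bond[, 1:2] > n)) return("bond endpoint out of range")
    if (any(g$bond[, 1L] == g$bond[, 2L])) return("self bond")
    key <- g$bond[, 1L] * (n + 1L) + g$bond[, 2L]
    if (anyDuplicated(key)) return("duplicate bond")
  }
  if (any(mg_valsum(g) > element_max_valence(g$elem))) return("valence exceeded")
  if (connectivity && !mg_connected(g)) return("disconnected")
  TRUE
}

mg_validate <- function(g, connectivity = TRUE) {
  ok <- mg_check(g, connectivity)
  if (!isTRUE(ok)) stop("invalid molecule: ", ok, call. = FALSE)
  invisible(g)
}

# implicit hydrogen count per atom
mg_implicit_h <- function(g) {
  pmax(element_default_valence(g$elem) - mg_valsum(g), 0L)
}

# average molecular weight including implicit hydrogens
mg_weight <- function(g) {
  sum(element_weight(g$elem)) + sum(mg_implicit_h(g)) * .H_WEIGHT
}

# ---- V2000 molblock serialization (zero coordinates; obabel re-perceives
# aromaticity from the kekule orders) ----

mg_molblock <- function(g, title = "") {
  n <- mg_natoms(g)
  m <- nrow(g$bond)
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    g$elem
  )
  bond_lines <- if (m) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bond[, 1L], g$bond[, 2L], g$bond[, 3L])
  } else character(0)
  paste(c(
    title, " molmorph", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    atom_lines, bond_lines, "M  END"
  ), collapse = "\n")
}

mg_sdf_batch <- function(graphs, ids) {
  paste0(paste(mapply(mg_molblock, graphs, ids), collapse = "\n$$$$\n"),
         "\n$$$$\n")
}

# Parse a multi-record V2000 SDF text (character vector of lines) into a
# list of (id, molgraph). Explicit hydrogens are stripped; charges,
# isotopes and radicals are rejected.
parse_sdf_lines <- function(lines) {
  recs <- list()
  start <- 1L
  nall <- length(lines)
  while (start <= nall) {
    stop_at <- start
    while (stop_at <= nall && !startsWith(lines[stop_at], "$$$$")) {
      stop_at <- stop_at + 1L
    }
    if (stop_at - start >= 4L) {
      block <- lines[start:(stop_at - 1L)]
      recs[[length(recs) + 1L]] <- block
    }
    start <- stop_at + 1L
  }
  lapply(recs, parse_molblock)
}

parse_molblock <- function(block) {
  id <- trimws(block[1L])
  counts <- block[4L]
  n <- as.integer(substr(counts, 1L, 3L))
  m <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n) || is.na(m)) stop("malformed molblock counts line", call. = FALSE)
  atom_lines <- block[5L:(4L + n)]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  bond <- matrix(integer(0), ncol = 3L)
  if (m > 0L) {
    bl <- block[(5L + n):(4L + n + m)]
    bond <- cbind(
      as.integer(substr(bl, 1L, 3L)),
      as.integer(substr(bl, 4L, 6L)),
      as.integer(substr(bl, 7L, 9L))
    )
  }
  props <- block[-seq_len(4L + n + m)]
  bad <- grep("^M  (CHG|ISO|RAD)", props, value = TRUE)
  if (length(bad)) {
    stop("charged, isotopic or radical species are not supported (",
         trimws(bad[[1L]]), ")", call. = FALSE)
  }
  # strip explicit hydrogens
  is_h <- elem %in% c("H", "D", "T")
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_along(elem), keep)
    if (nrow(bond)) {
      keep_bond <- !(is_h[bond[, 1L]] | is_h[bond[, 2L]])
      bond <- bond[keep_bond, , drop = FALSE]
      bond[, 1L] <- remap[bond[, 1L]]
      bond[, 2L] <- remap[bond[, 2L]]
    }
    elem <- elem[keep]
  }
  # aromatic bond order 4 should not appear (obabel writes kekule V2000),
  # but reject clearly if it does
  if (nrow(bond) && any(bond[, 3L] > 3L)) {
    stop("unkekulized (order-4) bond in molblock", call. = FALSE)
  }
  list(id = id, graph = mg_new(elem, bond))
}

# SMILES -> molgraph via obabel (batch). Returns a list of molgraphs named
# by id; missing ids mean obabel failed to parse that SMILES.
smiles_to_graphs <- function(smiles, ids = as.character(seq_along(smiles))) {
  lines <- ob_run(paste(smiles, ids), "smi", "sdf")
  parsed <- parse_sdf_lines(lines)
  out <- lapply(parsed, `[[`, "graph")
  names(out) <- vapply(parsed, `[[`, "", "id")
  out
}

# molgraph list -> canonical SMILES (batch); names = supplied ids
graphs_to_cansmi <- function(graphs, ids = as.character(seq_along(graphs))) {
  ob_canonical(mg_sdf_batch(graphs, ids), ids, from = "sdf")
}
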