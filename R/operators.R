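# Morphing operators: elementary structural edits turning a "reactant"
# molecule into a "product" molecule.
#
# All operators act on the kekule heavy-atom graph. Every enumerated site
# is guaranteed to yield a product that satisfies valence rules and stays a
# single connected component; apply_operator re-checks and errors on an
# inapplicable site rather than skipping silently.
#
# Codes: AA add atom, RA remove atom, AB add bond, RB remove bond,
# MA mutate atom, BR bond reroute, BC bond contraction, IA interlay atom.

.OPERATORS <- c("AA", "RA", "AB", "RB", "MA", "BR", "BC", "IA")

#' Morphing operator codes
#'
#' @param include_optional Include the interlay-atom operator `IA`
#'   (implemented, but excluded from the default operator set).
#' @return Character vector of two-letter operator codes.
#' @export
operator_kinds <- function(include_optional = FALSE) {
  if (include_optional) .OPERATORS else setdiff(.OPERATORS, "IA")
}

check_ops <- function(ops) {
  ops <- toupper(ops)
  bad <- setdiff(ops, .OPERATORS)
  if (length(bad)) {
    stop("unknown operator code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ops
}

#' Enumerate applicable sites for an operator
#'
#' Returns every site at which `op` can act on `mol` without violating
#' valence or connectivity. An empty list signals inapplicability.
#'
#' Site semantics:
#' * `AA` -- (atom with free valence) x (palette element): attach a new
#'   single-bonded atom.
#' * `RA` -- degree-1 atom: delete it (interior deletions are `BC`'s job, so
#'   connectivity never needs repair).
#' * `AB` -- atom pair, both with free valence: increment the bond order
#'   (up to triple) if already bonded, otherwise create a single bond.
#' * `RB` -- bond of order >= 2 (decrement), or an order-1 ring bond
#'   (delete; connectivity is preserved by ring membership).
#' * `MA` -- (atom, new element) with the new element's valence able to
#'   carry the atom's current bond-order sum.
#' * `BR` -- (bond, detached end, new attachment): the bond keeps its order
#'   and one end is moved to another atom with enough free valence; sites
#'   that would disconnect the graph are excluded.
#' * `BC` -- degree-2 atom whose two neighbours are not bonded to each
#'   other: delete the atom, single-bond the neighbours.
#' * `IA` -- (bond, palette element): replace the bond by two bonds of the
#'   same order through a new atom.
#'
#' @param mol `mol_record` or SMILES string.
#' @param op Operator code (see [operator_kinds()]).
#' @param palette Character vector of element symbols for `AA`, `MA`, `IA`;
#'   see [default_palette()].
#' @return List of site descriptors (named lists). Use
#'   [format_site()] for a textual rendering.
#' @export
enumerate_sites <- function(mol, op, palette = "C") {
  mol <- canonicalize(mol)
  sites_for_graph(mol$graph, check_ops(op), palette)
}

sites_for_graph <- function(g, op, palette = "C") {
  n <- mg_natoms(g)
  fv <- mg_free_valence(g)
  switch(op,
    AA = {
      out <- list()
      for (i in which(fv >= 1L)) {
        for (e in palette) {
          out[[length(out) + 1L]] <- list(atom = i, elem = e)
        }
      }
      out
    },
    RA = {
      if (n < 2L) return(list())
      lapply(which(mg_degree(g) == 1L), function(i) list(atom = i))
    },
    AB = {
      if (n < 2L) return(list())
      bkey <- paste(g$bond[, 1L], g$bond[, 2L])
      bord <- g$bond[, 3L]
      out <- list()
      for (i in seq_len(n - 1L)) {
        if (fv[i] < 1L) next
        for (j in seq.int(i + 1L, n)) {
          if (fv[j] < 1L) next
          k <- match(paste(i, j), bkey)
          if (!is.na(k) && bord[k] >= 3L) next
          out[[length(out) + 1L]] <- list(a = i, b = j)
        }
      }
      out
    },
    RB = {
      if (!nrow(g$bond)) return(list())
      ring <- mg_ring_bonds(g)
      ks <- which(g$bond[, 3L] >= 2L | ring)
      lapply(ks, function(k) list(bond = k))
    },
    MA = {
      vs <- mg_valsum(g)
      out <- list()
      for (i in seq_len(n)) {
        for (e in setdiff(palette, g$elem[i])) {
          if (element_default_valence(e) >= vs[i]) {
            out[[length(out) + 1L]] <- list(atom = i, elem = e)
          }
        }
      }
      out
    },
    BR = {
      if (!nrow(g$bond) || n < 3L) return(list())
      ring <- mg_ring_bonds(g)
      bkey <- paste(g$bond[, 1L], g$bond[, 2L])
      out <- list()
      for (k in seq_len(nrow(g$bond))) {
        u <- unname(g$bond[k, 1L]); v <- unname(g$bond[k, 2L])
        o <- unname(g$bond[k, 3L])
        for (ends in list(c(keep = u, detach = v), c(keep = v, detach = u))) {
          keep <- ends[["keep"]]; detach <- ends[["detach"]]
          # candidate receivers: enough free valence, not an endpoint, not
          # already bonded to the kept atom
          cand <- which(fv >= o)
          cand <- setdiff(cand, c(u, v))
          if (!length(cand)) next
          pk <- ifelse(pmin(keep, cand) == keep & pmax(keep, cand) == cand,
                       paste(keep, cand), paste(cand, keep))
          cand <- cand[is.na(match(pk, bkey))]
          if (!length(cand)) next
          if (!ring[k]) {
            # bridge bond: receiver must lie in the detached component
            comp <- mg_component_of(g, detach, drop_bond = k)
            cand <- intersect(cand, comp)
          }
          for (w in cand) {
            out[[length(out) + 1L]] <- list(bond = k, end = detach, to = w)
          }
        }
      }
      out
    },
    BC = {
      if (n < 3L) return(list())
      deg <- mg_degree(g)
      bkey <- paste(g$bond[, 1L], g$bond[, 2L])
      al <- mg_adjacency_list(g)
      out <- list()
      for (i in which(deg == 2L)) {
        nb <- sort(al[[i]])
        if (is.na(match(paste(nb[1L], nb[2L]), bkey))) {
          out[[length(out) + 1L]] <- list(atom = i)
        }
      }
      out
    },
    IA = {
      if (!nrow(g$bond)) return(list())
      out <- list()
      for (k in seq_len(nrow(g$bond))) {
        o <- g$bond[k, 3L]
        for (e in palette) {
          if (element_default_valence(e) >= 2L * o) {
            out[[length(out) + 1L]] <- list(bond = k, elem = e)
          }
        }
      }
      out
    },
    stop("unknown operator ", op, call. = FALSE)
  )
}

#' Render a site descriptor as text
#'
#' @param op Operator code.
#' @param site A site descriptor from [enumerate_sites()].
#' @return Single character string, e.g. `"AA:atom3+N"`.
#' @export
format_site <- function(op, site) {
  body <- switch(op,
    AA = paste0("atom", site$atom, "+", site$elem),
    RA = paste0("atom", site$atom),
    AB = paste0("atoms", site$a, "-", site$b),
    RB = paste0("bond", site$bond),
    MA = paste0("atom", site$atom, ">", site$elem),
    BR = paste0("bond", site$bond, ":", site$end, ">", site$to),
    BC = paste0("atom", site$atom),
    IA = paste0("bond", site$bond, "+", site$elem),
    stop("unknown operator ", op, call. = FALSE)
  )
  paste0(op, ":", body)
}

# site applicability check used by apply_graph_op (errors, not skips)
site_inapplicable <- function(op, site) {
  stop("operator ", op, " is not applicable at site ",
       format_site(op, site), call. = FALSE)
}

# Apply an operator to a molgraph. Sites must come from sites_for_graph on
# the same graph; preconditions are re-verified cheaply.
apply_graph_op <- function(g, op, site) {
  n <- mg_natoms(g)
  drop_atom <- function(g, i) {
    b <- g$bond
    keep <- b[, 1L] != i & b[, 2L] != i
    b <- b[keep, , drop = FALSE]
    b[, 1L] <- b[, 1L] - (b[, 1L] > i)
    b[, 2L] <- b[, 2L] - (b[, 2L] > i)
    mg_new(g$elem[-i], b)
  }
  out <- switch(op,
    AA = {
      i <- site$atom
      if (i > n || mg_free_valence(g)[i] < 1L) site_inapplicable(op, site)
      mg_new(c(g$elem, site$elem), rbind(g$bond, c(i, n + 1L, 1L)))
    },
    RA = {
      i <- site$atom
      if (n < 2L || i > n || mg_degree(g)[i] != 1L) site_inapplicable(op, site)
      drop_atom(g, i)
    },
    AB = {
      a <- site$a; b <- site$b
      if (max(a, b) > n) site_inapplicable(op, site)
      fv <- mg_free_valence(g)
      if (fv[a] < 1L || fv[b] < 1L) site_inapplicable(op, site)
      k <- which(g$bond[, 1L] == min(a, b) & g$bond[, 2L] == max(a, b))
      if (length(k)) {
        if (g$bond[k, 3L] >= 3L) site_inapplicable(op, site)
        bond <- g$bond
        bond[k, 3L] <- bond[k, 3L] + 1L
        mg_new(g$elem, bond)
      } else {
        mg_new(g$elem, rbind(g$bond, c(min(a, b), max(a, b), 1L)))
      }
    },
    RB = {
      k <- site$bond
      if (k > nrow(g$bond)) site_inapplicable(op, site)
      if (g$bond[k, 3L] >= 2L) {
        bond <- g$bond
        bond[k, 3L] <- bond[k, 3L] - 1L
        mg_new(g$elem, bond)
      } else {
        if (!mg_connected(g, drop_bond = k)) site_inapplicable(op, site)
        mg_new(g$elem, g$bond[-k, , drop = FALSE])
      }
    },
    MA = {
      i <- site$atom
      if (i > n || site$elem == g$elem[i] ||
          element_default_valence(site$elem) < mg_valsum(g)[i]) {
        site_inapplicable(op, site)
      }
      elem <- g$elem
      elem[i] <- site$elem
      mg_new(elem, g$bond)
    },
    BR = {
      k <- site$bond
      if (k > nrow(g$bond)) site_inapplicable(op, site)
      u <- g$bond[k, 1L]; v <- g$bond[k, 2L]; o <- g$bond[k, 3L]
      detach <- site$end; w <- site$to
      if (!detach %in% c(u, v) || w > n) site_inapplicable(op, site)
      keep <- if (detach == u) v else u
      if (w %in% c(u, v) || mg_free_valence(g)[w] < o) site_inapplicable(op, site)
      bond <- g$bond[-k, , drop = FALSE]
      if (any(bond[, 1L] == min(keep, w) & bond[, 2L] == max(keep, w))) {
        site_inapplicable(op, site)
      }
      g2 <- mg_new(g$elem, rbind(bond, c(keep, w, o)))
      if (!mg_connected(g2)) site_inapplicable(op, site)
      g2
    },
    BC = {
      i <- site$atom
      if (n < 3L || i > n || mg_degree(g)[i] != 2L) site_inapplicable(op, site)
      nb <- sort(mg_adjacency_list(g)[[i]])
      if (any(g$bond[, 1L] == nb[1L] & g$bond[, 2L] == nb[2L])) {
        site_inapplicable(op, site)
      }
      g2 <- drop_atom(g, i)
      nb2 <- nb - (nb > i)
      mg_new(g2$elem, rbind(g2$bond, c(nb2[1L], nb2[2L], 1L)))
    },
    IA = {
      k <- site$bond
      if (k > nrow(g$bond)) site_inapplicable(op, site)
      o <- g$bond[k, 3L]
      if (element_default_valence(site$elem) < 2L * o) site_inapplicable(op, site)
      u <- g$bond[k, 1L]; v <- g$bond[k, 2L]
      bond <- g$bond[-k, , drop = FALSE]
      mg_new(c(g$elem, site$elem),
             rbind(bond, c(u, n + 1L, o), c(v, n + 1L, o)))
    },
    stop("unknown operator ", op, call. = FALSE)
  )
  # connectivity holds by construction: only RB deletions and BR can break
  # it and both verify it at site level above
  mg_validate(out, connectivity = FALSE)
  out
}

new_morph_result <- function(product, op, site, parent_id) {
  structure(list(
    product = product,
    operator = op,
    site = format_site(op, site),
    parent_id = parent_id
  ), class = "morph_result")
}

#' @export
print.morph_result <- function(x, ...) {
  cat("<morph_result> ", x$parent_id, " --[", x$operator, "]--> ",
      x$product$canonical_form, "  (", x$site, ")\n", sep = "")
  invisible(x)
}

#' Apply a morphing operator at a given site
#'
#' @param mol `mol_record` or SMILES string (the parent; left unmodified).
#' @param op Operator code.
#' @param site Site descriptor from [enumerate_sites()] on the same
#'   molecule.
#' @return A `morph_result`: `product` (`mol_record`), `operator`, `site`
#'   (textual descriptor) and `parent_id` (parent canonical form).
#' @export
apply_operator <- function(mol, op, site) {
  mol <- canonicalize(mol)
  op <- check_ops(op)
  g2 <- apply_graph_op(mol$graph, op, site)
  new_morph_result(record_from_graph(g2), op, site, mol$canonical_form)
}

# one random (op, site) draw over cached site lists; returns NULL on failure
draw_graph_morph <- function(g, enabled, palette, site_cache, max_retries = 10L) {
  for (trial in seq_len(max_retries)) {
    op <- enabled[[sample.int(length(enabled), 1L)]]
    if (is.null(site_cache[[op]])) {
      site_cache[[op]] <- sites_for_graph(g, op, palette)
    }
    sites <- site_cache[[op]]
    if (!length(sites)) next
    site <- sites[[sample.int(length(sites), 1L)]]
    return(list(op = op, site = site))
  }
  # exhaustive fallback: fail only when genuinely no operator applies
  for (op in enabled) {
    if (is.null(site_cache[[op]])) {
      site_cache[[op]] <- sites_for_graph(g, op, palette)
    }
    sites <- site_cache[[op]]
    if (length(sites)) {
      return(list(op = op, site = sites[[sample.int(length(sites), 1L)]]))
    }
  }
  NULL
}

#' Random single morph
#'
#' Picks an operator uniformly from `enabled`, then a site uniformly among
#' that operator's applicable sites (retrying across operators when the
#' drawn one has no site). Returns `NULL` -- a failure value, not an error --
#' only when no enabled operator admits any edit.
#'
#' @param mol `mol_record` or SMILES string.
#' @param enabled Character vector of operator codes.
#' @param palette Element palette.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `morph_result` or `NULL`.
#' @export
random_morph <- function(mol, enabled = operator_kinds(), palette = "C",
                         seed = NULL) {
  mol <- canonicalize(mol)
  enabled <- check_ops(enabled)
  if (!length(enabled)) stop("'enabled' must be non-empty", call. = FALSE)
  if (!is.null(seed)) local_seed(seed)
  cache <- new.env(parent = emptyenv())
  draw <- draw_graph_morph(mol$graph, enabled, palette, cache)
  if (is.null(draw)) return(NULL)
  apply_operator(mol, draw$op, draw$site)
}

# Internal bulk generation: n_gen random draws on one parent graph;
# returns list of list(graph, op, site) WITHOUT canonicalization so the
# caller can batch it across parents. `cache` may carry site enumerations
# for this graph across calls.
morph_graphs <- function(g, n_gen, enabled, palette, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  out <- vector("list", n_gen)
  n_out <- 0L
  for (r in seq_len(n_gen)) {
    draw <- draw_graph_morph(g, enabled, palette, cache)
    if (is.null(draw)) break
    g2 <- tryCatch(apply_graph_op(g, draw$op, draw$site),
                   error = function(e) NULL)
    if (is.null(g2)) next
    n_out <- n_out + 1L
    out[[n_out]] <- list(graph = g2, op = draw$op, site = draw$site)
  }
  out[seq_len(n_out)]
}

#' Generate a deduplicated set of morphs from one parent
#'
#' Draws `n_gen` random operator applications from `parent` and returns the
#' distinct products (by canonical form), excluding the parent itself.
#'
#' @param parent `mol_record` or SMILES string.
#' @param n_gen Number of random draws (>= 1).
#' @param enabled Operator codes.
#' @param palette Element palette.
#' @param seed Optional integer seed.
#' @return List of `morph_result`; empty when the parent admits no edit.
#' @export
generate_morphs <- function(parent, n_gen = 80L, enabled = operator_kinds(),
                            palette = "C", seed = NULL) {
  stopifnot(n_gen >= 1L)
  parent <- canonicalize(parent)
  enabled <- check_ops(enabled)
  if (!is.null(seed)) local_seed(seed)
  raw <- morph_graphs(parent$graph, n_gen, enabled, palette)
  if (!length(raw)) return(list())
  cans <- unname(graphs_to_cansmi(lapply(raw, `[[`, "graph")))
  idx <- which(!duplicated(cans) & cans != parent$canonical_form)
  lapply(idx, function(i) {
    new_morph_result(
      record_from_graph(raw[[i]]$graph, canonical_form = cans[[i]]),
      raw[[i]]$op, raw[[i]]$site, parent$canonical_form
    )
  })
}

# set.seed local to the calling function, restoring the caller's RNG state
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
}
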