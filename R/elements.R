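# Element model for the heavy-atom graph.
#
# default_valence drives implicit-hydrogen counting and the free-valence
# arithmetic used by the morphing operators; max_valence is the validation
# cap, so hypervalent but common groups (sulfones, phosphates, pentavalent
# kekule nitro) parse without being editable beyond their default valence.

.ELEMENTS <- data.frame(
  symbol          = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
  weight          = c(12.011, 14.007, 15.999, 32.06, 30.974,
                      18.998, 35.45, 79.904, 126.904),
  default_valence = c(4L, 3L, 2L, 2L, 3L, 1L, 1L, 1L, 1L),
  max_valence     = c(4L, 5L, 2L, 6L, 5L, 1L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)
.H_WEIGHT <- 1.008

#' Supported elements
#'
#' Returns the element table used by the molecular model: atomic weight,
#' default valence (implicit hydrogen filling and operator free-valence
#' arithmetic) and maximum tolerated valence (validation cap).
#'
#' @return A data frame with columns `symbol`, `weight`, `default_valence`
#'   and `max_valence`.
#' @export
element_table <- function() .ELEMENTS

element_idx <- function(symbols) {
  i <- match(symbols, .ELEMENTS$symbol)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(symbols[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  i
}

element_default_valence <- function(symbols) {
  .ELEMENTS$default_valence[element_idx(symbols)]
}

element_max_valence <- function(symbols) {
  .ELEMENTS$max_valence[element_idx(symbols)]
}

element_weight <- function(symbols) .ELEMENTS$weight[element_idx(symbols)]

#' Default element palette for morphing operators
#'
#' The pool of elements new or mutated atoms may take. By default the
#' palette is derived from the target molecule: every element present in it,
#' plus carbon, so mutation chemistry is steered toward the target without a
#' hand-tuned pool.
#'
#' @param target A [MoleculeRecord][canonicalize], or `NULL` for a
#'   carbon-only palette.
#' @return Character vector of element symbols.
#' @export
default_palette <- function(target = NULL) {
  if (is.null(target)) return("C")
  stopifnot(inherits(target, "mol_record"))
  sort(unique(c("C", names(target$element_multiset))))
}
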