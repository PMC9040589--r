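# Element-weighted (carbon / nitrogen) mass-flow networks.
#
# A cross-fed metabolite's molar exchange is converted to atom flow by
# multiplying the exchanged concentration (mM) by the number of C or N
# atoms per molecule, giving element-mmol per liter of culture. Edges below
# a display cutoff (default 0.1 element-mmol/L) are dropped.

#' Element flow of one metabolite exchange
#'
#' @param delta_conc Exchanged concentration in mM (>= 0).
#' @param counts Element counts (or formula string) of the metabolite.
#' @param element `"C"` or `"N"`.
#' @return Flow in element-mmol per liter; 0 when the molecule contains no
#'   atoms of the element.
#' @examples
#' element_flow(14.7, "C4H6O4", "C") # succinate: 58.8 C-mmol/L
#' @export
element_flow <- function(delta_conc, counts, element = c("C", "N")) {
  element <- match.arg(element)
  if (is.na(delta_conc) || delta_conc < 0) {
    stop("delta_conc must be a non-negative concentration (mM)")
  }
  if (is.character(counts)) counts <- parse_formula(counts)
  n_atoms <- if (element %in% names(counts)) counts[[element]] else 0L
  delta_conc * n_atoms
}

#' Build an element-specific mass-flow network
#'
#' Converts a quantified cross-feeding edge list to atom flows for one
#' element. The edge quantity is the amount the consumer removed in the
#' producer's spent medium (`consumed_mM`). Edges whose metabolite lacks
#' the element, or whose flow does not exceed `min_flow`, are dropped;
#' edges without a quantified amount are skipped with a warning and
#' counted.
#'
#' @param edges CrossFeedEdge data.frame with a `consumed_mM` column.
#' @param database A `formula_db` (see [formula_db()]); every quantified
#'   edge's metabolite must resolve by name.
#' @param element `"C"` or `"N"`.
#' @param min_flow Display cutoff in element-mmol/L (default 0.1); edges
#'   with flow <= `min_flow` are removed.
#' @return list with `edges` (`producer`, `consumer`, `metabolite`,
#'   `element`, `flow`), `totals` (per species `out_flow` as provider,
#'   `in_flow` as consumer), and `n_unquantified`.
#' @export
build_element_network <- function(edges, database, element = c("C", "N"),
                                  min_flow = 0.1) {
  element <- match.arg(element)
  check_columns(edges, c("producer", "consumer", "metabolite",
                         "consumed_mM"), "edge list")
  unquant <- is.na(edges$consumed_mM)
  if (any(unquant)) {
    warning(sum(unquant), " edge(s) lack a quantified amount; skipped")
  }
  q <- edges[!unquant, , drop = FALSE]
  missing <- setdiff(unique(q$metabolite), database$name)
  if (length(missing) > 0L) {
    stop("metabolite(s) missing from formula database: ",
         paste(missing, collapse = ", "))
  }
  atom_count <- vapply(q$metabolite, function(m) {
    counts <- parse_formula(database$formula[match(m, database$name)])
    if (element %in% names(counts)) counts[[element]] else 0L
  }, integer(1))
  flow <- q$consumed_mM * atom_count
  keep <- flow > min_flow
  fe <- data.frame(producer = q$producer[keep], consumer = q$consumer[keep],
                   metabolite = q$metabolite[keep], element = element,
                   flow = flow[keep], stringsAsFactors = FALSE)
  rownames(fe) <- NULL
  species <- sort(unique(c(fe$producer, fe$consumer)))
  totals <- data.frame(
    species = species,
    out_flow = vapply(species, function(s) sum(fe$flow[fe$producer == s]),
                      numeric(1)),
    in_flow = vapply(species, function(s) sum(fe$flow[fe$consumer == s]),
                     numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(edges = fe, totals = totals, n_unquantified = sum(unquant))
}
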