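# Gut metabolic module (GMM) detection from ortholog lists.
#
# A module is an ordered list of steps; a step is satisfied when any of its
# alternative orthologs is present in the genome. Coverage is the fraction
# of satisfied steps, and a module is called present at coverage strictly
# greater than the detection threshold (>50% by default). Nested boolean
# module grammars must be flattened to this step/alternative form upstream.

#' Read flattened metabolic-module definitions
#'
#' Expects a TSV with columns `module_id`, `step_index`, `ortholog_id`
#' (one row per alternative ortholog per step) and optionally `name`.
#'
#' @param path TSV path.
#' @return Named list of `ModuleDefinition`s: each a list with `id`, `name`,
#'   `steps` (list of character vectors of alternative orthologs).
#' @export
read_module_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("module_id", "step_index", "ortholog_id"),
                "module definition table")
  if (!"name" %in% names(df)) df$name <- df$module_id
  defs <- lapply(split(df, df$module_id), function(d) {
    steps <- lapply(split(d$ortholog_id, d$step_index), unique)
    module_definition(d$module_id[1], d$name[1], unname(steps))
  })
  defs
}

#' Construct a metabolic-module definition
#'
#' @param id Module identifier.
#' @param name Human-readable name.
#' @param steps List of non-empty character vectors; each vector holds the
#'   alternative orthologs satisfying that step.
#' @return A `module_definition` list.
#' @export
module_definition <- function(id, name = id, steps) {
  if (length(steps) == 0L) stop("module must have at least one step: ", id)
  if (any(vapply(steps, length, integer(1)) == 0L)) {
    stop("empty step in module ", id)
  }
  structure(list(id = id, name = name, steps = steps),
            class = "module_definition")
}

#' Detect metabolic modules in a genome's ortholog set
#'
#' @param ortholog_set Character vector of ortholog identifiers present in
#'   the genome (e.g., KEGG KO ids).
#' @param definitions List of [module_definition()]s (or the result of
#'   [read_module_definitions()]).
#' @param threshold Coverage detection threshold in (0, 1); a module is
#'   present when coverage is strictly greater (default 0.5, i.e. >50%).
#' @return data.frame with `module_id`, `name`, `n_steps`, `n_satisfied`,
#'   `coverage`, `present`.
#' @export
detect_modules <- function(ortholog_set, definitions, threshold = 0.5) {
  if (length(definitions) == 0L) stop("empty module definitions")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ortholog_set <- unique(as.character(ortholog_set))
  rows <- lapply(definitions, function(def) {
    sat <- vapply(def$steps, function(step) any(step %in% ortholog_set),
                  logical(1))
    cov <- sum(sat) / length(sat)
    data.frame(module_id = def$id, name = def$name,
               n_steps = length(sat), n_satisfied = sum(sat),
               coverage = cov, present = cov > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
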