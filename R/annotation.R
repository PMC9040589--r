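# Accurate-mass annotation of negative-mode ions against a formula database.
#
# Masses are monoisotopic (most abundant isotope), in Da. The ion species is
# the singly deprotonated anion [M - H]-, so the measured m/z is the neutral
# monoisotopic mass minus the mass of a proton (1.007276 Da), not minus the
# mass of a hydrogen atom. The electron mass (~0.00055 Da) is far below the
# working tolerance and is not corrected for.

#' Monoisotopic atomic masses (Da)
#'
#' Masses of the most abundant stable isotope for the elements that occur in
#' common metabolite formulas, used for neutral-mass and m/z computation.
#'
#' @format Named numeric vector, element symbol -> mass in Da.
#' @export
MONOISOTOPIC_MASS <- c(
  C  = 12.000000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370693,
  Cl = 34.96885271,
  Br = 78.9183376,
  I  = 126.904473,
  F  = 18.99840320,
  Se = 79.9165218,
  Mg = 23.98504170,
  Ca = 39.96259098,
  Fe = 55.93493633,
  Zn = 63.92914201,
  B  = 11.0093055,
  Si = 27.97692653
)

#' Mass of a proton (Da), subtracted for the [M - H]- species.
#' @export
PROTON_MASS <- 1.007276

# Heavy-minus-light monoisotopic mass differences for stable-isotope labels.
ISOTOPE_SHIFT <- c(C = 1.003355, N = 0.997035, H = 1.006277)

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula ("C4H6O4") into a named vector of
#' element counts. An omitted count means 1. Unknown element symbols and
#' malformed tokens are errors.
#'
#' @param formula Character scalar, e.g. `"C6H14N4O2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C4H6O4")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a non-empty character scalar")
  }
  # tokens: element symbol (capital + optional lowercase) + optional count
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  cnts <- ifelse(nzchar(cnts), as.integer(cnts), 1L)
  unknown <- setdiff(syms, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Format element counts as a Hill-order formula
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical when no carbon is present). Counts of 1 are omitted;
#' zero-count elements are dropped.
#'
#' @param counts Named integer vector as returned by [parse_formula()].
#' @return Character scalar.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty element counts")
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Neutral monoisotopic mass of a formula
#'
#' @param counts Named integer vector of element counts, or a formula string.
#' @return Mass in Da.
#' @export
neutral_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (any(counts < 0)) stop("negative element count")
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(counts * MONOISOTOPIC_MASS[names(counts)])
}

#' m/z of the singly deprotonated ion [M - H]-
#'
#' @param counts Element counts or formula string.
#' @param strict_h If `TRUE`, require at least one hydrogen (the proton must
#'   come from somewhere); default `FALSE` to allow bookkeeping on fragments.
#' @return m/z in Da.
#' @examples
#' mz_deprotonated("C4H6O4") # succinate, ~117.0193
#' @export
mz_deprotonated <- function(counts, strict_h = FALSE) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (strict_h && (!"H" %in% names(counts) || counts[["H"]] < 1L)) {
    stop("deprotonation requires at least one hydrogen")
  }
  neutral_mass(counts) - PROTON_MASS
}

#' Expected m/z of an isotope-labeled [M - H]- ion
#'
#' Shifts the deprotonated m/z by `n_labeled` heavy-minus-light mass
#' differences (13C-12C = 1.003355 Da, 15N-14N = 0.997035 Da).
#'
#' @param counts Element counts or formula string.
#' @param label Element being labeled, `"C"` or `"N"` (or `"H"` for
#'   deuterium).
#' @param n_labeled Number of labeled atoms; must not exceed the atom count
#'   of that element.
#' @return m/z in Da.
#' @examples
#' labeled_mz("C4H6O4", "C", 4) - mz_deprotonated("C4H6O4") # ~4.01342
#' @export
labeled_mz <- function(counts, label, n_labeled) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (!label %in% names(ISOTOPE_SHIFT)) {
    stop("unsupported label element: ", label)
  }
  n_labeled <- as.integer(n_labeled)
  if (n_labeled < 0L) stop("n_labeled must be >= 0")
  avail <- if (label %in% names(counts)) counts[[label]] else 0L
  if (n_labeled > avail) {
    stop("n_labeled (", n_labeled, ") exceeds ", label, " atom count (",
         avail, ")")
  }
  mz_deprotonated(counts) + n_labeled * ISOTOPE_SHIFT[[label]]
}

#' Read a metabolite formula database
#'
#' Reads a tab-separated file with columns `name`, `formula` and (optionally)
#' `class`. The neutral monoisotopic mass and the [M - H]- m/z are computed
#' from the formula, never trusted from the file.
#'
#' @param path Path to a TSV file.
#' @return A `formula_db` data.frame with columns `name`, `formula`, `class`,
#'   `neutral_mass`, `mz_mh`.
#' @export
read_formula_db <- function(path) {
  db <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("name", "formula")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0L) {
    stop("formula database lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"class" %in% names(db)) db$class <- NA_character_
  formula_db(db$name, db$formula, db$class)
}

#' Build a formula database from vectors
#'
#' @param name Metabolite names.
#' @param formula Molecular formulas (Hill style).
#' @param class Optional compound classes.
#' @return A `formula_db` data.frame.
#' @export
formula_db <- function(name, formula, class = NA_character_) {
  stopifnot(length(name) == length(formula))
  nm <- vapply(formula, function(f) neutral_mass(parse_formula(f)),
               numeric(1), USE.NAMES = FALSE)
  db <- data.frame(
    name = as.character(name),
    formula = as.character(formula),
    class = rep_len(as.character(class), length(name)),
    neutral_mass = nm,
    mz_mh = nm - PROTON_MASS,
    stringsAsFactors = FALSE
  )
  class(db) <- c("formula_db", "data.frame")
  db
}

#' Annotate measured m/z values by accurate mass
#'
#' Matches each measured m/z against the deprotonated masses of a formula
#' database. Every record within the tolerance is returned (isobaric
#' compounds with identical formulas are indistinguishable by accurate mass
#' alone and are all reported). Candidates are ordered by absolute mass
#' error, ties broken alphabetically by name.
#'
#' @param mz Numeric vector of measured m/z values (negative mode, [M - H]-).
#' @param database A `formula_db` data.frame.
#' @param tolerance Mass tolerance in Da; default 0.003 (flow-injection
#'   accuracy). Use 0.001 for matching isotope-labeled ions measured by
#'   LC-MS.
#' @return A data.frame with one row per (mz, candidate): columns `mz`,
#'   `name`, `formula`, `class`, `mass_error_da`. m/z values with no match
#'   are absent from the result.
#' @export
annotate_ions <- function(mz, database, tolerance = 0.003) {
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  if (nrow(database) == 0L) stop("empty formula database")
  out <- lapply(mz, function(m) {
    err <- m - database$mz_mh
    hit <- abs(err) <= tolerance
    if (!any(hit)) return(NULL)
    d <- data.frame(
      mz = m,
      name = database$name[hit],
      formula = database$formula[hit],
      class = database$class[hit],
      mass_error_da = err[hit],
      stringsAsFactors = FALSE
    )
    d[order(abs(d$mass_error_da), d$name), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mz = numeric(0), name = character(0),
                      formula = character(0), class = character(0),
                      mass_error_da = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
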