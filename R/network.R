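# Cross-feeding network construction and statistics.
#
# Two complementary views are built from the dynamic calls:
#   * a fresh-medium prediction: metabolites secreted by at least one
#     species and consumed by at least one other in monocultures on fresh
#     medium are potentially cross-fed;
#   * a spent-medium network: a directed edge (producer, consumer,
#     metabolite) requires the metabolite to be secreted by the producer in
#     fresh medium AND consumed by the consumer while growing in that
#     producer's spent medium — direct evidence of transfer.

interaction_type <- function(n_producers, n_consumers) {
  if (n_producers == 1L && n_consumers == 1L) "one-to-one"
  else if (n_producers == 1L) "one-to-many"
  else if (n_consumers == 1L) "many-to-one"
  else "many-to-many"
}

#' Predict potentially cross-fed metabolites from fresh-medium calls
#'
#' A metabolite is potentially cross-fed when it is secreted by at least one
#' species and consumed by at least one *different* species in fresh-medium
#' monocultures. The interaction type follows from the producer and consumer
#' set sizes: (1,1) one-to-one, (1,>=2) one-to-many, (>=2,1) many-to-one,
#' (>=2,>=2) many-to-many. A species may appear in both sets (e.g.,
#' transient overflow metabolism) but a metabolite secreted and consumed
#' only by the same single species is excluded.
#'
#' @param calls Dynamic-call data.frame (see [call_dynamics()]) restricted
#'   to fresh-medium cultures; rows with `medium != "fresh"` are dropped
#'   with a warning unless `medium = NULL`.
#' @param medium Medium identifier to filter on (default `"fresh"`); `NULL`
#'   to use all rows as-is.
#' @return data.frame with one row per cross-fed metabolite: `metabolite`,
#'   `producers`, `consumers` (comma-joined, sorted), `n_producers`,
#'   `n_consumers`, `interaction_type`.
#' @export
predict_fresh_crossfeeding <- function(calls, medium = "fresh") {
  check_columns(calls, c("metabolite", "species", "direction"), "call table")
  if (!is.null(medium) && "medium" %in% names(calls)) {
    other <- calls$medium != medium
    if (any(other)) {
      warning(sum(other), " non-", medium, " rows dropped")
      calls <- calls[!other, , drop = FALSE]
    }
  }
  if (nrow(calls) == 0L) return(empty_summary())
  mets <- sort(unique(calls$metabolite))
  rows <- lapply(mets, function(m) {
    sub <- calls[calls$metabolite == m, ]
    producers <- sort(unique(sub$species[sub$direction == "secreted"]))
    consumers <- sort(unique(sub$species[sub$direction == "consumed"]))
    if (length(producers) == 0L || length(consumers) == 0L) return(NULL)
    # needs at least one producer-consumer pair of distinct species
    if (length(producers) == 1L && length(consumers) == 1L &&
        producers == consumers) return(NULL)
    data.frame(metabolite = m,
               producers = paste(producers, collapse = ","),
               consumers = paste(consumers, collapse = ","),
               n_producers = length(producers),
               n_consumers = length(consumers),
               interaction_type = interaction_type(length(producers),
                                                   length(consumers)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_summary())
  rownames(out) <- NULL
  out
}

empty_summary <- function() {
  data.frame(metabolite = character(0), producers = character(0),
             consumers = character(0), n_producers = integer(0),
             n_consumers = integer(0), interaction_type = character(0),
             stringsAsFactors = FALSE)
}

#' Extract the producer species from a spent-medium identifier
#'
#' Spent-medium cultures are identified as `"spent:<producer>"` throughout
#' the package.
#'
#' @param medium Character vector of medium identifiers.
#' @return Producer species, `NA` for non-spent media.
#' @export
spent_producer <- function(medium) {
  ifelse(startsWith(medium, "spent:"), sub("^spent:", "", medium),
         NA_character_)
}

#' Build the spent-medium cross-feeding network
#'
#' An edge (P, C, m) is created when metabolite m has a secreted call for
#' producer P in fresh medium and a consumed call for consumer C growing in
#' P's spent medium, with P != C. Each (producer, consumer, metabolite)
#' triple appears at most once.
#'
#' @param fresh_calls Dynamic calls on fresh-medium cultures.
#' @param spent_calls Dynamic calls on spent-medium cultures; the medium
#'   column must be `"spent:<producer>"`.
#' @param known_producers Optional character vector of valid producer
#'   species; spent media referencing other producers are an error.
#' @return data.frame of `CrossFeedEdge`s: `producer`, `consumer`,
#'   `metabolite`, `medium`, `consumed_mM` (NA until quantified).
#' @export
build_spent_network <- function(fresh_calls, spent_calls,
                                known_producers = NULL) {
  check_columns(fresh_calls, c("metabolite", "species", "direction"),
                "fresh call table")
  check_columns(spent_calls, c("metabolite", "species", "medium",
                               "direction"), "spent call table")
  spent <- spent_calls[spent_calls$direction == "consumed", , drop = FALSE]
  spent$producer <- spent_producer(spent$medium)
  if (any(is.na(spent$producer))) {
    stop("spent call table contains non-spent medium id(s): ",
         paste(unique(spent$medium[is.na(spent$producer)]), collapse = ", "))
  }
  if (!is.null(known_producers)) {
    bad <- setdiff(unique(spent$producer), known_producers)
    if (length(bad) > 0L) {
      stop("spent medium references unknown producer(s): ",
           paste(bad, collapse = ", "))
    }
  }
  secreted <- fresh_calls[fresh_calls$direction == "secreted",
                          c("metabolite", "species")]
  names(secreted) <- c("metabolite", "producer")
  edges <- merge(unique(secreted),
                 unique(spent[c("metabolite", "species", "producer",
                                "medium")]),
                 by = c("metabolite", "producer"))
  names(edges)[names(edges) == "species"] <- "consumer"
  edges <- edges[edges$producer != edges$consumer, ]
  edges <- unique(edges[c("producer", "consumer", "metabolite", "medium")])
  edges$consumed_mM <- rep(NA_real_, nrow(edges))
  edges <- edges[order(edges$producer, edges$consumer, edges$metabolite), ]
  rownames(edges) <- NULL
  edges
}

#' Public/private goods and consumption:secretion scores
#'
#' Aggregates a cross-feeding edge list per metabolite (producer and
#' consumer sets, interaction type, public good when consumed by two or
#' more distinct species) and per species (number of consuming and
#' producing interactions and their ratio; species that never produce get
#' `NA` ratio, species that never consume get ratio 0).
#'
#' @param edges CrossFeedEdge data.frame (see [build_spent_network()]).
#' @param classes Optional named character vector metabolite -> compound
#'   class, carried into the summaries for enrichment tests.
#' @return list with `summaries` and `scores` data.frames.
#' @export
goods_and_scores <- function(edges, classes = NULL) {
  check_columns(edges, c("producer", "consumer", "metabolite"), "edge list")
  mets <- sort(unique(edges$metabolite))
  summaries <- do.call(rbind, lapply(mets, function(m) {
    sub <- edges[edges$metabolite == m, ]
    producers <- sort(unique(sub$producer))
    consumers <- sort(unique(sub$consumer))
    data.frame(metabolite = m,
               producers = paste(producers, collapse = ","),
               consumers = paste(consumers, collapse = ","),
               n_producers = length(producers),
               n_consumers = length(consumers),
               interaction_type = interaction_type(length(producers),
                                                   length(consumers)),
               good_class = if (length(consumers) >= 2L) "public"
                            else "private",
               compound_class = if (!is.null(classes) && m %in% names(classes))
                 classes[[m]] else NA_character_,
               n_edges = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summaries)) {
    summaries <- cbind(empty_summary(),
                       data.frame(good_class = character(0),
                                  compound_class = character(0),
                                  n_edges = integer(0)))
  }
  species <- sort(unique(c(edges$producer, edges$consumer)))
  scores <- do.call(rbind, lapply(species, function(sp) {
    n_con <- sum(edges$consumer == sp)
    n_sec <- sum(edges$producer == sp)
    data.frame(species = sp, n_consumed = n_con, n_secreted = n_sec,
               ratio = if (n_sec > 0) n_con / n_sec
                       else if (n_con == 0) 0 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(scores)) {
    scores <- data.frame(species = character(0), n_consumed = integer(0),
                         n_secreted = integer(0), ratio = numeric(0))
  }
  rownames(summaries) <- rownames(scores) <- NULL
  list(summaries = summaries, scores = scores)
}

#' Enrichment and covariate statistics on a cross-feeding network
#'
#' Tests whether a compound class is enriched among public goods (two-sided
#' Fisher exact test on the 2x2 table class-membership x public/private,
#' metabolites without a class excluded), and correlates per-species
#' consumed-metabolite counts with a species covariate such as genome size
#' (Pearson).
#'
#' @param summaries Metabolite summaries from [goods_and_scores()] with
#'   `good_class` and `compound_class` columns.
#' @param species_covariate Named numeric vector species -> covariate value
#'   (e.g., genome size in Mb); `NULL` to skip the correlation.
#' @param enrich_class Compound class to test (e.g.,
#'   `"carboxylic acid"`); `NULL` to skip the enrichment test.
#' @return list with `enrichment` (`odds_ratio`, `p`, `table`) and
#'   `covariate` (`r`, `n`, per-species counts).
#' @export
network_statistics <- function(summaries, species_covariate = NULL,
                               enrich_class = NULL) {
  enrichment <- NULL
  if (!is.null(enrich_class)) {
    s <- summaries[!is.na(summaries$compound_class), , drop = FALSE]
    if (nrow(s) == 0L) stop("no metabolite has a compound class")
    is_pub <- s$good_class == "public"
    if (all(is_pub) || !any(is_pub)) {
      enrichment <- list(odds_ratio = NA_real_, p = NA_real_, table = NULL,
                         skipped = "degenerate margins: all goods are one class")
    } else {
      in_class <- s$compound_class == enrich_class
      tab <- matrix(c(sum(in_class & is_pub), sum(!in_class & is_pub),
                      sum(in_class & !is_pub), sum(!in_class & !is_pub)),
                    nrow = 2,
                    dimnames = list(class = c("in", "out"),
                                    good = c("public", "private")))
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      enrichment <- list(odds_ratio = unname(ft$estimate), p = ft$p.value,
                         table = tab)
    }
  }
  covariate <- NULL
  if (!is.null(species_covariate)) {
    counts <- consumed_metabolite_counts(summaries)
    # species in the network that consume nothing count as zero
    all_species <- unique(unlist(strsplit(
      c(summaries$producers, summaries$consumers), ",")))
    counts <- stats::setNames(
      ifelse(all_species %in% names(counts), counts[all_species], 0),
      all_species)
    common <- intersect(names(counts), names(species_covariate))
    if (length(common) < 3L) stop("need >= 3 species with covariate values")
    x <- counts[common]
    y <- species_covariate[common]
    if (stats::sd(y) == 0) stop("zero-variance covariate")
    covariate <- list(r = stats::cor(x, y), n = length(common), counts = x)
  }
  list(enrichment = enrichment, covariate = covariate)
}

# Number of distinct cross-fed metabolites each species consumes.
consumed_metabolite_counts <- function(summaries) {
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    data.frame(species = strsplit(summaries$consumers[i], ",")[[1]],
               metabolite = summaries$metabolite[i],
               stringsAsFactors = FALSE)
  })))
  tab <- table(pairs$species)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Export a cross-feeding or flow network as GraphML
#'
#' Species are nodes; each edge carries its metabolite (and any additional
#' numeric attributes present, e.g. `flow` or `consumed_mM`).
#'
#' @param edges data.frame with `producer`, `consumer` and attribute
#'   columns.
#' @param path Output file path.
#' @return The igraph object, invisibly.
#' @export
write_network_graphml <- function(edges, path) {
  check_columns(edges, c("producer", "consumer"), "edge list")
  g <- igraph::graph_from_data_frame(
    edges[c("producer", "consumer",
            setdiff(names(edges), c("producer", "consumer")))],
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Infer cross-feeding edges directly from an ion time-course table
#'
#' Convenience wrapper: calls dynamics on the fresh-medium and spent-medium
#' subsets of a combined table and builds the spent-medium network.
#'
#' @param table Combined ion time-course table containing `"fresh"` and
#'   `"spent:<producer>"` media.
#' @param config A [caller_config()].
#' @return CrossFeedEdge data.frame.
#' @export
infer_crossfeeding <- function(table, config = caller_config()) {
  fresh <- table[table$medium == "fresh", , drop = FALSE]
  spent <- table[startsWith(table$medium, "spent:"), , drop = FALSE]
  if (nrow(fresh) == 0L || nrow(spent) == 0L) {
    stop("table must contain both fresh and spent-medium cultures")
  }
  build_spent_network(call_dynamics(fresh, config),
                      call_dynamics(spent, config),
                      known_producers = unique(table$species))
}
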