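# End-to-end orchestration: annotation -> growth -> dynamics (fresh) ->
# dynamics (spent) -> network -> elemental flows -> metabolic potential,
# from a flat key-value configuration file, writing every table to an
# output directory together with a run manifest.

#' Read a flat key-value pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys:
#' `ion_table`, `formula_db`, `concentration_table`, `module_definitions`,
#' `ortholog_dir`, `genome_sizes`, `enrich_class`, `tolerance`, `min_flow`,
#' `seed`, `out_dir`, and the caller thresholds (`r_od_threshold`,
#' `p_threshold`, `r2_fit_threshold`, `fc_secreted`, `fc_consumed`,
#' `dilution_corr_threshold`).
#'
#' @param path Configuration file path.
#' @return A named list (`pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad) > 0L) stop("malformed config line(s): ",
                             paste(bad, collapse = "; "))
  cfg <- stats::setNames(lapply(kv, function(m) trimws(m[3])),
                         vapply(kv, function(m) m[2], character(1)))
  numeric_keys <- c("tolerance", "min_flow", "seed", "r_od_threshold",
                    "p_threshold", "r2_fit_threshold", "fc_secreted",
                    "fc_consumed", "dilution_corr_threshold")
  for (k in intersect(names(cfg), numeric_keys)) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Named list of configuration values.
#' @return The validated list, classed `pipeline_config`.
#' @export
pipeline_config <- function(cfg) {
  required <- c("ion_table", "formula_db", "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0L) {
    stop("configuration lacks required field(s): ",
         paste(missing, collapse = ", "))
  }
  for (k in intersect(names(cfg), c("ion_table", "formula_db",
                                    "concentration_table",
                                    "module_definitions", "genome_sizes"))) {
    if (!file.exists(cfg[[k]])) {
      stop("configured path for '", k, "' does not exist: ", cfg[[k]])
    }
  }
  defaults <- list(tolerance = 0.003, min_flow = 0.1, seed = 1,
                   enrich_class = NA_character_)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

config_caller <- function(cfg) {
  args <- list()
  for (k in c("r_od_threshold", "p_threshold", "r2_fit_threshold",
              "fc_secreted", "fc_consumed", "dilution_corr_threshold")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(caller_config, args)
}

#' Run the cross-feeding inference pipeline
#'
#' Executes all stages on the configured inputs and writes every result
#' table (TSV), the species networks (GraphML) and a run manifest into
#' `cfg$out_dir`. Deterministic: identical configuration and inputs give
#' identical outputs.
#'
#' @param cfg A [pipeline_config()] or path to a config file.
#' @param force Overwrite an existing output directory.
#' @return The `ReportBundle` (named list of all result tables), invisibly.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  out <- cfg$out_dir
  if (dir.exists(out) && !force &&
      length(list.files(out)) > 0L) {
    stop("output directory not empty (use force = TRUE): ", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[crossfeedr] ", ...)

  db <- read_formula_db(cfg$formula_db)
  log_stage("annotation: formula database with ", nrow(db), " records")

  table <- read_ion_table(cfg$ion_table)
  fits <- fit_growth_table(table)
  write_tsv(fits, file.path(out, "growth_fits.tsv"))
  log_stage("growth: ", nrow(fits), " culture fits")

  config <- config_caller(cfg)
  fresh_tab <- table[table$medium == "fresh", , drop = FALSE]
  spent_tab <- table[startsWith(table$medium, "spent:"), , drop = FALSE]
  fresh_calls <- call_dynamics(fresh_tab, config)
  write_tsv(fresh_calls, file.path(out, "calls_fresh.tsv"))
  log_stage("dynamics (fresh): ",
            sum(fresh_calls$direction != "unchanged"), " directional calls")
  spent_calls <- if (nrow(spent_tab) > 0L) call_dynamics(spent_tab, config)
                 else NULL
  if (!is.null(spent_calls)) {
    write_tsv(spent_calls, file.path(out, "calls_spent.tsv"))
    log_stage("dynamics (spent): ",
              sum(spent_calls$direction != "unchanged"), " directional calls")
  }

  fresh_pred <- predict_fresh_crossfeeding(fresh_calls)
  write_tsv(fresh_pred, file.path(out, "fresh_predictions.tsv"))
  log_stage("network: ", nrow(fresh_pred),
            " potentially cross-fed metabolites (fresh)")

  edges <- summaries <- scores <- stats_out <- NULL
  if (!is.null(spent_calls)) {
    edges <- build_spent_network(fresh_calls, spent_calls,
                                 known_producers = unique(table$species))
    if (!is.null(cfg$concentration_table) &&
        !is.na(cfg$concentration_table)) {
      conc <- read_concentration_table(cfg$concentration_table)
      edges <- quantify_edges(edges, conc)
    }
    classes <- stats::setNames(db$class, db$name)
    gs <- goods_and_scores(edges, classes = classes)
    summaries <- gs$summaries
    scores <- gs$scores
    write_tsv(edges, file.path(out, "edges.tsv"))
    write_tsv(summaries, file.path(out, "metabolite_summaries.tsv"))
    write_tsv(scores, file.path(out, "species_scores.tsv"))
    if (nrow(edges) > 0L) {
      write_network_graphml(edges, file.path(out, "network.graphml"))
    }
    log_stage("network: ", nrow(edges), " cross-feeding edges, ",
              nrow(summaries), " metabolites")

    covariate <- NULL
    if (!is.null(cfg$genome_sizes)) {
      gsz <- read_tsv(cfg$genome_sizes)
      covariate <- stats::setNames(gsz[[2]], gsz[[1]])
    }
    enrich <- if (!is.na(cfg$enrich_class)) cfg$enrich_class else NULL
    if (!is.null(covariate) || !is.null(enrich)) {
      stats_out <- network_statistics(summaries, covariate, enrich)
    }

    if (any(!is.na(edges$consumed_mM))) {
      for (el in c("C", "N")) {
        net <- build_element_network(edges, db, el,
                                     min_flow = cfg$min_flow)
        write_tsv(net$edges, file.path(out, paste0("flows_", el, ".tsv")))
        write_tsv(net$totals,
                  file.path(out, paste0("flow_totals_", el, ".tsv")))
        if (nrow(net$edges) > 0L) {
          write_network_graphml(net$edges,
                                file.path(out, paste0("network_", el,
                                                      ".graphml")))
        }
        log_stage("elemental_flow (", el, "): ", nrow(net$edges), " edges")
      }
    }
  }

  modules <- NULL
  if (!is.null(cfg$module_definitions) && !is.null(cfg$ortholog_dir)) {
    defs <- read_module_definitions(cfg$module_definitions)
    files <- list.files(cfg$ortholog_dir, full.names = TRUE)
    modules <- do.call(rbind, lapply(files, function(f) {
      genome <- sub("\\.[^.]*$", "", basename(f))
      det <- detect_modules(readLines(f, warn = FALSE), defs)
      cbind(genome = genome, det)
    }))
    write_tsv(modules, file.path(out, "modules.tsv"))
    log_stage("metabolic_potential: ", length(files), " genomes")
  }

  manifest <- c(
    paste0("package_version = ", as.character(utils::packageVersion("crossfeedr"))),
    paste0("r_version = ", R.version.string),
    paste0("seed = ", cfg$seed),
    paste0("ion_table_md5 = ", unname(tools::md5sum(cfg$ion_table))),
    paste0("formula_db_md5 = ", unname(tools::md5sum(cfg$formula_db)))
  )
  writeLines(manifest, file.path(out, "run_manifest.txt"))

  invisible(list(growth_fits = fits, fresh_calls = fresh_calls,
                 spent_calls = spent_calls, fresh_predictions = fresh_pred,
                 edges = edges, summaries = summaries, scores = scores,
                 statistics = stats_out, modules = modules, config = cfg))
}

#' Attach consumed amounts (mM) to cross-feeding edges
#'
#' For each edge, the consumed amount is the concentration at the earliest
#' sampled time minus the minimum concentration over the consumer's culture
#' in the producer's spent medium. Edges without matching quantification
#' rows keep `NA`.
#'
#' @param edges CrossFeedEdge data.frame.
#' @param conc Concentration table (see [read_concentration_table()]).
#' @return The edge data.frame with `consumed_mM` filled where quantified.
#' @export
quantify_edges <- function(edges, conc) {
  check_columns(conc, c("metabolite", "species", "medium", "time_h",
                        "conc_mM"), "concentration table")
  for (i in seq_len(nrow(edges))) {
    sub <- conc[conc$metabolite == edges$metabolite[i] &
                conc$species == edges$consumer[i] &
                conc$medium == edges$medium[i], , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$time_h), ]
    edges$consumed_mM[i] <- max(0, sub$conc_mM[1] - min(sub$conc_mM))
  }
  edges
}
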