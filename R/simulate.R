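# Seeded synthetic-data generator with known ground truth.
#
# Emulates the structure of batch monoculture exometabolomics: logistic
# growth, metabolite trajectories yield-coupled to biomass gain,
# multiplicative lognormal measurement noise (ion counts are positive and
# heteroscedastic), medium dilution series, and spent-medium transfer
# experiments (producer supernatant mixed 1:1 with fresh medium before the
# consumer is inoculated).

#' Four-parameter logistic curve
#'
#' `OD(t) = A + (K - A) / (1 + exp(-r (t - t0)))` with baseline `A`,
#' asymptote `K`, shape rate `r` (1/h) and inflection time `t0` (h).
#'
#' @param t Time (h).
#' @param A,K,r,t0 Curve parameters.
#' @return OD at `t`.
#' @export
logistic4 <- function(t, A, K, r, t0) {
  A + (K - A) / (1 + exp(-r * (t - t0)))
}

# Multiplicative lognormal noise factors with mean 1 and coefficient of
# variation cv. cv = 0 returns exact 1s.
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise_cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a batch growth curve
#'
#' @param params Named vector or list with `A`, `K`, `r`, `t0` (OD baseline,
#'   OD asymptote, shape rate in 1/h, inflection time in h). Requires
#'   `K >= A > 0`.
#' @param times Strictly increasing sampling times (h).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise; 0 for a noiseless curve.
#' @param seed Optional integer seed (set locally, does not disturb the
#'   caller's RNG state).
#' @return data.frame with columns `time_h`, `od`.
#' @export
simulate_growth <- function(params, times, noise_cv = 0, seed = NULL) {
  params <- as.list(params)
  if (length(times) == 0L || any(diff(times) <= 0)) {
    stop("times must be non-empty and strictly increasing")
  }
  if (params$A <= 0 || params$K < params$A) stop("requires K >= A > 0")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  od <- logistic4(times, params$A, params$K, params$r, params$t0)
  od <- od * lognormal_noise(length(times), noise_cv)
  data.frame(time_h = times, od = od)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Specify a synthetic community experiment
#'
#' Defines species growth parameters, the fresh-medium composition, the
#' per-species metabolite interactions and the sampling design from which
#' fresh-medium and spent-medium time courses are simulated.
#'
#' Consumption is parameterized as the fraction (in \[0, 1\]) of the
#' initially available amount that is consumed over the full biomass gain;
#' the trajectory follows normalized OD gain, so a fraction near 1 with a
#' steep curve approximates exhaustion. Secretion is an intensity gain per
#' unit OD increase.
#'
#' @param species Character vector of species identifiers.
#' @param growth Named list (per species) of `c(A, K, r, t0)` parameters.
#' @param medium Named numeric vector: fresh-medium metabolite levels
#'   (arbitrary ion-intensity units, or mM for quantified runs).
#' @param interactions Named list (per species) of lists with elements
#'   `consume` (named fractions in \[0,1\]) and `secrete` (named
#'   non-negative yields per unit OD gain).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param times Sampling times (h), strictly increasing.
#' @param replicates Number of replicate cultures.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `community_spec` object.
#' @export
community_spec <- function(species, growth, medium, interactions,
                           noise_cv = 0.05, times = NULL, replicates = 3,
                           seed = 1) {
  if (is.null(times)) {
    # roughly log-spaced sampling: dense early, sparse in stationary phase
    times <- round(exp(seq(log(1), log(24), length.out = 10)), 2)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(all(species %in% names(growth)))
  secreted_anywhere <- unique(unlist(lapply(
    interactions, function(x) names(x$secrete)[x$secrete > 0])))
  for (sp in names(interactions)) {
    ia <- interactions[[sp]]
    cy <- ia$consume
    if (length(cy) > 0 && (any(cy < 0) || any(cy > 1))) {
      stop("consumption fractions must be in [0, 1] (species ", sp, ")")
    }
    if (length(ia$secrete) > 0 && any(ia$secrete < 0)) {
      stop("secretion yields must be >= 0 (species ", sp, ")")
    }
    orphan <- setdiff(names(cy)[cy > 0],
                      c(names(medium), secreted_anywhere))
    if (length(orphan) > 0) {
      stop("consumed metabolite(s) neither in medium nor secreted by any ",
           "species: ", paste(orphan, collapse = ", "))
    }
  }
  for (sp in species) {
    g <- as.list(growth[[sp]])
    if (g$A <= 0 || g$K < g$A) stop("growth requires K >= A > 0: ", sp)
  }
  structure(list(species = species, growth = growth, medium = medium,
                 interactions = interactions, noise_cv = noise_cv,
                 times = times, replicates = replicates,
                 seed = as.integer(seed)),
            class = "community_spec")
}

# All metabolites that can ever appear in any culture of this community.
spec_metabolites <- function(spec) {
  sec <- unlist(lapply(spec$interactions, function(x) names(x$secrete)))
  con <- unlist(lapply(spec$interactions, function(x) names(x$consume)))
  unique(c(names(spec$medium), sec, con))
}

# Deterministic noiseless endpoint exometabolome of `sp` grown in `medium0`.
endpoint_exometabolome <- function(spec, sp, medium0) {
  g <- as.list(spec$growth[[sp]])
  traj <- metabolite_trajectories(spec, sp, medium0,
                                  od = logistic4(spec$times, g$A, g$K, g$r,
                                                 g$t0))
  traj[nrow(traj), , drop = TRUE]
}

# Noiseless metabolite level matrix (time x metabolite) for one culture.
# Consumed: x(t) = x0 (1 - y * gain(t)), gain normalized to [0,1] by the
# asymptotic biomass increment. Secreted: x(t) = x0 + s * (OD(t) - OD(0)).
metabolite_trajectories <- function(spec, sp, medium0, od) {
  g <- as.list(spec$growth[[sp]])
  mets <- spec_metabolites(spec)
  x0 <- stats::setNames(rep(0, length(mets)), mets)
  x0[names(medium0)] <- medium0
  ia <- spec$interactions[[sp]]
  gain <- (od - od[1]) / (g$K - od[1])
  dod <- od - od[1]
  out <- matrix(rep(x0, each = length(od)), nrow = length(od),
                dimnames = list(NULL, mets))
  for (m in names(ia$consume)) {
    y <- ia$consume[[m]]
    if (y > 0) out[, m] <- x0[[m]] * (1 - y * gain)
  }
  for (m in names(ia$secrete)) {
    s <- ia$secrete[[m]]
    if (s > 0) out[, m] <- out[, m] + s * dod
  }
  as.data.frame(out)
}

#' Simulate one culture's exometabolome time course
#'
#' In `"fresh"` mode the species grows in the fresh medium. In `"spent"`
#' mode the producer's noiseless endpoint exometabolome is computed first,
#' mixed 1:1 with fresh medium, and the (different) consumer species is then
#' simulated in that mixture.
#'
#' @param spec A [community_spec()].
#' @param species Species to culture.
#' @param mode `"fresh"` or `"spent"`.
#' @param producer Producer species whose supernatant is used
#'   (required in spent mode).
#' @return list with `table` (rows: replicate x time, columns `species`,
#'   `medium`, `replicate`, `time_h`, `od`, one column per metabolite) and
#'   `medium0` (the initial composition used).
#' @export
simulate_culture <- function(spec, species, mode = c("fresh", "spent"),
                             producer = NULL) {
  mode <- match.arg(mode)
  if (mode == "spent") {
    if (is.null(producer)) stop("spent mode requires a producer")
    endpoint <- endpoint_exometabolome(spec, producer, spec$medium)
    mets <- names(endpoint)
    fresh <- stats::setNames(rep(0, length(mets)), mets)
    fresh[names(spec$medium)] <- spec$medium
    medium0 <- (fresh + unlist(endpoint)) / 2
    medium_id <- paste0("spent:", producer)
  } else {
    medium0 <- spec$medium
    medium_id <- "fresh"
  }
  g <- as.list(spec$growth[[species]])
  reps <- lapply(seq_len(spec$replicates), function(rep_i) {
    od0 <- logistic4(spec$times, g$A, g$K, g$r, g$t0)
    traj <- metabolite_trajectories(spec, species, medium0, od0)
    od <- od0 * lognormal_noise(length(od0), spec$noise_cv)
    noise <- matrix(lognormal_noise(length(od0) * ncol(traj), spec$noise_cv),
                    nrow = length(od0))
    traj <- traj * noise
    cbind(data.frame(species = species, medium = medium_id,
                     replicate = rep_i, time_h = spec$times, od = od,
                     stringsAsFactors = FALSE),
          traj)
  })
  list(table = do.call(rbind, reps), medium0 = medium0)
}

#' Ground truth of a community specification
#'
#' @param spec A [community_spec()].
#' @return list with `secreted` and `consumed` (data.frames of
#'   species/metabolite) and `edges` (data.frame producer/consumer/
#'   metabolite: producer secretes it and a different consumer consumes it).
#' @export
ground_truth <- function(spec) {
  sec <- do.call(rbind, lapply(spec$species, function(sp) {
    s <- spec$interactions[[sp]]$secrete
    s <- s[s > 0]
    if (length(s) == 0) return(NULL)
    data.frame(species = sp, metabolite = names(s), stringsAsFactors = FALSE)
  }))
  con <- do.call(rbind, lapply(spec$species, function(sp) {
    y <- spec$interactions[[sp]]$consume
    y <- y[y > 0]
    if (length(y) == 0) return(NULL)
    data.frame(species = sp, metabolite = names(y), stringsAsFactors = FALSE)
  }))
  empty <- data.frame(species = character(0), metabolite = character(0))
  if (is.null(sec)) sec <- empty
  if (is.null(con)) con <- empty
  edges <- merge(stats::setNames(sec, c("producer", "metabolite")),
                 stats::setNames(con, c("consumer", "metabolite")),
                 by = "metabolite")
  edges <- edges[edges$producer != edges$consumer,
                 c("producer", "consumer", "metabolite")]
  edges <- edges[order(edges$producer, edges$consumer, edges$metabolite), ]
  rownames(edges) <- NULL
  list(secreted = sec, consumed = con, edges = edges)
}

#' Simulate the full fresh + spent-medium experiment set
#'
#' Reproduces the design the inference pipeline expects: every species grown
#' in fresh medium, and every species grown in every other species' spent
#' medium (1:1 mixture with fresh medium). Fully seeded; identical seeds
#' give identical tables.
#'
#' @param spec A [community_spec()].
#' @return list with `table` (combined ion time-course table) and `truth`
#'   (see [ground_truth()]).
#' @export
simulate_consortium <- function(spec) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  tabs <- list()
  for (sp in spec$species) {
    tabs[[length(tabs) + 1L]] <- simulate_culture(spec, sp, "fresh")$table
  }
  for (prod in spec$species) {
    for (cons in setdiff(spec$species, prod)) {
      tabs[[length(tabs) + 1L]] <-
        simulate_culture(spec, cons, "spent", producer = prod)$table
    }
  }
  list(table = do.call(rbind, tabs), truth = ground_truth(spec))
}

#' Simulate a medium dilution series
#'
#' Medium-derived ions respond proportionally to 1/dilution; background ions
#' (instrument or solvent derived) are constant across dilutions. Used to
#' calibrate fold-change thresholds for the dynamic caller.
#'
#' @param medium_ions Named numeric vector: undiluted intensity of
#'   medium-derived ions.
#' @param background_ions Named numeric vector: intensity of
#'   dilution-independent background ions.
#' @param dilutions Numeric vector of fold-dilution factors (> 0), at least
#'   two distinct values.
#' @param replicates Replicate measurements per dilution.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Optional integer seed.
#' @return data.frame with columns `dilution`, `replicate`, one column per
#'   ion.
#' @export
simulate_dilution_series <- function(medium_ions, background_ions = NULL,
                                     dilutions, replicates = 3,
                                     noise_cv = 0, seed = NULL) {
  if (length(medium_ions) + length(background_ions) == 0L) {
    stop("no ions to simulate")
  }
  if (any(dilutions <= 0) || length(unique(dilutions)) < 2L) {
    stop("need at least two distinct positive dilution factors")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  grid <- expand.grid(replicate = seq_len(replicates), dilution = dilutions)
  ions <- c(medium_ions, background_ions)
  vals <- sapply(names(ions), function(ion) {
    base <- ions[[ion]]
    ideal <- if (ion %in% names(medium_ions)) base / grid$dilution
             else rep(base, nrow(grid))
    ideal * lognormal_noise(nrow(grid), noise_cv)
  })
  vals <- matrix(vals, nrow = nrow(grid),
                 dimnames = list(NULL, names(ions)))
  cbind(data.frame(dilution = grid$dilution, replicate = grid$replicate),
        as.data.frame(vals))
}

#' Draw a randomized community specification
#'
#' Generates a consortium of `n_species` species with randomized but
#' realistic batch-growth parameters (baseline OD ~0.05, plateaus between
#' 0.8 and 2 OD, rates 0.5-1.5 /h, inflections 3-8 h), a shared rich medium
#' of `n_substrates` consumable components, one to two secreted products
#' per species, and randomized cross-feeding: each product is consumed by a
#' random subset of the other species (at least one consumer for the first
#' product, so the truth network is never empty). Consumption fractions are
#' drawn in 0.5-0.95 and secretion yields in 100-500 intensity units per
#' unit OD.
#'
#' @param n_species Number of species (>= 2).
#' @param n_substrates Number of shared medium substrates.
#' @param noise_cv Multiplicative measurement-noise CV.
#' @param replicates Replicate cultures per condition.
#' @param times Sampling times (h).
#' @param seed Integer seed; fully determines the specification.
#' @return A [community_spec()].
#' @export
random_community_spec <- function(n_species = 5, n_substrates = 6,
                                  noise_cv = 0.05, replicates = 3,
                                  times = seq(1, 24, length.out = 10),
                                  seed = 1) {
  stopifnot(n_species >= 2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  species <- paste0("sp", seq_len(n_species))
  growth <- lapply(species, function(sp) {
    c(A = stats::runif(1, 0.03, 0.08), K = stats::runif(1, 0.8, 2.0),
      r = stats::runif(1, 0.5, 1.5), t0 = stats::runif(1, 3, 8))
  })
  names(growth) <- species
  substrates <- paste0("substrate", seq_len(n_substrates))
  medium <- stats::setNames(stats::runif(n_substrates, 600, 2000),
                            substrates)
  products <- lapply(species, function(sp) {
    paste0("prod_", sp, "_", seq_len(sample(1:2, 1)))
  })
  names(products) <- species
  # a rich medium already contains some of the metabolites that community
  # members secrete; include each product at a modest background level with
  # 30% probability so that fresh-medium monocultures can also reveal
  # consumption of other species' products
  for (m in unlist(products)) {
    if (stats::runif(1) < 0.3) {
      medium[m] <- stats::runif(1, 100, 400)
    }
  }
  interactions <- stats::setNames(vector("list", n_species), species)
  for (sp in species) {
    consume <- stats::setNames(
      stats::runif(2, 0.5, 0.95),
      sample(substrates, 2))
    secrete <- stats::setNames(
      stats::runif(length(products[[sp]]), 100, 500), products[[sp]])
    interactions[[sp]] <- list(consume = consume, secrete = secrete)
  }
  first <- TRUE
  for (sp in species) {
    for (m in products[[sp]]) {
      others <- setdiff(species, sp)
      consumers <- others[stats::runif(length(others)) < 0.5]
      if (first && length(consumers) == 0L) consumers <- sample(others, 1)
      first <- FALSE
      for (cons in consumers) {
        interactions[[cons]]$consume[m] <- stats::runif(1, 0.5, 0.9)
      }
    }
  }
  community_spec(species = species, growth = growth, medium = medium,
                 interactions = interactions, noise_cv = noise_cv,
                 times = times, replicates = replicates, seed = seed)
}
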