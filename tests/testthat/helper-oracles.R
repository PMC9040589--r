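# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles (base R
# statistical functions, exhaustive enumeration) rather than calling any
# crossfeedr internals.

# Brute-force evaluation of the dynamic-caller decision rule for a single
# averaged intensity series. Mirrors the documented rule but is coded
# independently: cor.test / lm for the statistics, explicit loops for the
# fold changes.
oracle_call <- function(intensity, od, time, cfg) {
  if (sd(intensity) == 0 || all(intensity <= 0)) return("unchanged")
  floor_pos <- function(x) {
    if (any(x <= 0)) x[x <= 0] <- min(x[x > 0]) / 2
    x
  }
  xf <- floor_pos(intensity)
  up <- max(sapply(seq_along(xf), function(i) xf[i] / xf[1]))
  down <- max(sapply(seq_along(xf), function(i) xf[1] / xf[i]))

  crit <- list()  # list of (pass, sign)
  if (sd(od) > 0) {
    ct <- cor.test(intensity, od)
    crit$cor <- c(pass = unname(abs(ct$estimate) > cfg$r_od_threshold &&
                    ct$p.value < cfg$p_threshold),
                  sign = unname(sign(ct$estimate)))
  }
  fit_branch <- function(y) {
    sm <- suppressWarnings(summary(lm(y ~ time)))
    c(pass = sm$r.squared > cfg$r2_fit_threshold &&
        sm$coefficients[2, 4] < cfg$p_threshold,
      sign = sign(sm$coefficients[2, 1]))
  }
  crit$lin <- fit_branch(intensity)
  crit$exp <- fit_branch(log(floor_pos(intensity)))

  pos <- any(sapply(crit, function(k) k[["pass"]] == 1 && k[["sign"]] > 0))
  neg <- any(sapply(crit, function(k) k[["pass"]] == 1 && k[["sign"]] < 0))
  sec <- pos && up >= cfg$fc_secreted
  con <- neg && down >= cfg$fc_consumed
  if (sec && con) {
    if (up >= down) "secreted" else "consumed"
  } else if (sec) "secreted" else if (con) "consumed" else "unchanged"
}

# Exhaustive two-sided Fisher exact p for a 2x2 table: sum the
# hypergeometric probabilities of all tables with the observed margins
# whose probability does not exceed the observed one (within the same
# relative tolerance R's fisher.test uses).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b       # row-1 margin
  n <- c + d
  k <- a + c       # col-1 margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Linear-scan annotation oracle: every record within tolerance, ordered by
# absolute error then name.
oracle_annotate <- function(mz, db, tol) {
  hits <- list()
  for (i in seq_len(nrow(db))) {
    err <- mz - db$mz_mh[i]
    if (abs(err) <= tol) {
      hits[[length(hits) + 1L]] <- data.frame(
        name = db$name[i], err = err, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(character(0))
  h <- do.call(rbind, hits)
  h$name[order(abs(h$err), h$name)]
}

# Precision/recall of an inferred edge set against a truth edge set, on
# producer|consumer|metabolite triples.
edge_prf <- function(inferred, truth) {
  key <- function(e) paste(e$producer, e$consumer, e$metabolite, sep = "|")
  ik <- key(inferred); tk <- key(truth)
  tp <- length(intersect(ik, tk))
  c(precision = if (length(ik) == 0) 1 else tp / length(ik),
    recall = if (length(tk) == 0) 1 else tp / length(tk))
}
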