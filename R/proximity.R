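#' Network proximity between drug targets and disease proteins
#'
#' The benchmark score against which the feature-based classifier is
#' compared: the mean, over drug targets, of the shortest hop distance to the
#' closest disease protein, z-scored against a null distribution of random
#' protein sets matched in size and degree. A closer-than-expected
#' drug-target set (negative z) indicates likely efficacy.
#'
#' @name proximity
NULL

# undirected simple igraph view of the knowledge graph, memoised in the
# graph's cache environment (shared by reference across copies)
.kg_igraph <- function(graph) {
  cached <- get0("igraph", envir = graph$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  tr <- graph$triples
  el <- unique(data.frame(
    from = pmin(tr$subject, tr$object),
    to = pmax(tr$subject, tr$object), stringsAsFactors = FALSE))
  el <- el[el$from != el$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = graph$proteins)
  assign("igraph", g, envir = graph$cache)
  g
}

#' Unweighted shortest hop distances between two protein sets
#'
#' Orientation is ignored; self-relationship triples do not shorten paths.
#' Proteins absent from the graph or in a different component get `Inf`.
#'
#' @param graph a [kg_graph()]
#' @param sources,targets character vectors of protein ids
#' @return Numeric matrix of hop counts, rows = `sources`, cols = `targets`.
#' @export
shortest_hop_distances <- function(graph, sources, targets) {
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  D <- matrix(Inf, length(sources), length(targets),
              dimnames = list(sources, targets))
  src_in <- intersect(sources, graph$proteins)
  tgt_in <- intersect(targets, graph$proteins)
  if (length(src_in) && length(tgt_in)) {
    g <- .kg_igraph(graph)
    D[src_in, tgt_in] <- igraph::distances(g, v = src_in, to = tgt_in)
  }
  D
}

#' Mean closest hop distance from drug targets to disease proteins
#'
#' For each drug target, the distance to its closest disease protein; the
#' score is the mean over drug targets. Targets with no finite distance to
#' any disease protein are excluded from the mean (and listed), rather than
#' assigned an arbitrary penalty; set `unreachable_penalty` to a finite hop
#' count to include them at that fixed distance instead.
#'
#' @param graph a [kg_graph()]
#' @param dt,dp character vectors: drug-target and disease-protein ids
#' @param unreachable_penalty optional finite distance substituted for
#'   unreachable targets (default `NULL`: exclude them)
#' @return List with `d_c` (mean closest distance, `NA` when every target is
#'   unreachable), `per_target` (named vector of per-target minima),
#'   `excluded` (targets dropped from the mean) and `disconnected` flag.
#' @export
closest_distance <- function(graph, dt, dp, unreachable_penalty = NULL) {
  D <- shortest_hop_distances(graph, dt, dp)
  mins <- apply(D, 1L, min)
  finite <- is.finite(mins)
  used <- mins
  if (!is.null(unreachable_penalty)) {
    used[!finite] <- unreachable_penalty
    finite <- rep(TRUE, length(mins))
  }
  list(d_c = if (any(finite)) mean(used[finite]) else NA_real_,
       per_target = mins,
       excluded = names(mins)[!finite],
       disconnected = !any(finite))
}

# Degree bins for the randomization null: proteins are grouped by degree,
# merging adjacent degree values (ascending) until each bin holds at least
# `min_bin` proteins; the trailing remainder is merged into the last bin.
.degree_bins <- function(graph, min_bin = 100L) {
  g <- .kg_igraph(graph)
  deg <- igraph::degree(g)
  n <- length(deg)
  if (n == 0L) stop("graph has no proteins")
  if (min_bin > n) {
    warning("fewer proteins (", n, ") than the minimum bin size (", min_bin,
            "); using a single degree bin")
    min_bin <- n
  }
  by_deg <- split(names(deg), deg)  # names sorted by numeric degree
  bins <- list()
  current <- character()
  for (members in by_deg) {
    current <- c(current, members)
    if (length(current) >= min_bin) {
      bins[[length(bins) + 1L]] <- current
      current <- character()
    }
  }
  if (length(current)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], current)
    else bins[[1L]] <- current
  }
  bin_of <- integer(0)
  for (b in seq_along(bins)) bin_of[bins[[b]]] <- b
  list(bins = bins, bin_of = bin_of)
}

# one random set degree-matched to `proteins`, distinct members
.sample_matched_set <- function(proteins, binning) {
  picked <- character(length(proteins))
  for (i in seq_along(proteins)) {
    b <- binning$bin_of[[proteins[i]]]
    cand <- setdiff(binning$bins[[b]], picked)
    if (!length(cand)) cand <- setdiff(unlist(binning$bins), picked)
    picked[i] <- cand[sample.int(length(cand), 1L)]
  }
  picked
}

#' Proximity z-score against a degree-matched random null
#'
#' Draws `n_random` pairs of random protein sets matched to the sizes and
#' degree-bin profile of the drug-target and disease-protein sets (bins of at
#' least `min_bin` proteins, grown over adjacent degree values), recomputes
#' the mean closest distance for each draw, and standardizes the observed
#' distance: `z = (d_c - null_mean) / null_sd`. Deterministic for a given
#' seed. Proteins missing from the graph contribute no distances and are
#' matched from the lowest-degree bin.
#'
#' @inheritParams closest_distance
#' @param n_random number of random draws (>= 100; default 1000)
#' @param seed integer RNG seed
#' @param min_bin minimum proteins per degree bin (default 100; reduced with
#'   a warning on small graphs)
#' @return Object of class `kg_proximity`: list with `d_c`, `z`, `null_mean`,
#'   `null_sd`, `n_random`, `n_null_used`, `disconnected`.
#' @export
proximity_z <- function(graph, dt, dp, n_random = 1000L, seed = 1L,
                        min_bin = 100L) {
  if (n_random < 100L) stop("n_random must be at least 100")
  obs <- closest_distance(graph, dt, dp)
  binning <- .degree_bins(graph, min_bin)
  dt <- unique(as.character(dt))
  dp <- unique(as.character(dp))
  lowest <- binning$bins[[1L]][1L]
  match_in <- function(set) {
    known <- intersect(set, names(binning$bin_of))
    c(known, rep(lowest, length(set) - length(known)))
  }
  dt_m <- match_in(dt)
  dp_m <- match_in(dp)
  set.seed(seed)
  null_d <- vapply(seq_len(n_random), function(i) {
    closest_distance(graph,
                     .sample_matched_set(dt_m, binning),
                     .sample_matched_set(dp_m, binning))$d_c
  }, 0)
  used <- null_d[is.finite(null_d)]
  null_mean <- if (length(used)) mean(used) else NA_real_
  null_sd <- if (length(used) > 1L) stats::sd(used) else NA_real_
  z <- if (!is.na(obs$d_c) && !is.na(null_sd) && null_sd > 0)
    (obs$d_c - null_mean) / null_sd else NA_real_
  structure(list(d_c = obs$d_c, z = z, null_mean = null_mean,
                 null_sd = null_sd, n_random = n_random,
                 n_null_used = length(used),
                 disconnected = obs$disconnected),
            class = "kg_proximity")
}

#' @export
print.kg_proximity <- function(x, ...) {
  cat(sprintf("<kg_proximity> d_c = %.3f, z = %.3f (null %.3f +/- %.3f, %d draws)\n",
              x$d_c, x$z, x$null_mean, x$null_sd, x$n_random))
  invisible(x)
}

#' Proximity scores for a list of combinations
#'
#' Scores each combination with `-z` (higher = closer than expected = more
#' likely efficacious), ready for ROC analysis. Combinations with no finite
#' distance or an undefined z receive the worst finite score minus one, so
#' they rank strictly below every connected combination.
#'
#' @param graph a [kg_graph()]
#' @param combos list of [combination()] objects
#' @param n_random,seed,min_bin passed to [proximity_z()]; the per-combo seed
#'   is `seed + index`
#' @return data.frame: combo_id, label, d_c, null_mean, null_sd, z, score.
#' @export
proximity_score_combos <- function(graph, combos, n_random = 1000L, seed = 1L,
                                   min_bin = 100L) {
  res <- lapply(seq_along(combos), function(i) {
    cb <- combos[[i]]
    p <- proximity_z(graph, cb$drug_targets, cb$disease_proteins,
                     n_random = n_random, seed = seed + i, min_bin = min_bin)
    data.frame(combo_id = cb$combo_id, label = cb$label, d_c = p$d_c,
               null_mean = p$null_mean, null_sd = p$null_sd, z = p$z,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df$score <- -df$z
  bad <- !is.finite(df$score)
  if (any(bad))
    df$score[bad] <- if (all(bad)) 0 else min(df$score[!bad]) - 1
  df
}
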