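#' Configuration for the synthetic knowledge-graph benchmark
#'
#' The generator emulates the statistical shape of a large commercial
#' protein-level knowledge graph — thousands of proteins, a heavy-tailed
#' degree distribution, edges carrying several predicate types each attested
#' by several sources, 45 predicate types and 25 sources at full scale — and
#' reference sets whose drug-target sets have median size 2 and whose
#' disease-protein sets have median size about 5, matching the published
#' reference-set characteristics.
#'
#' Class signal is *planted*: positive and negative combinations are built by
#' the identical structural process (same set sizes, same number and mix of
#' planted overlap/direct/indirect paths), so co-occurrence rates carry no
#' class information by construction; only the predicate and provenance
#' labels on planted path triples differ. A planted triple of a positive
#' combination draws a designated signal predicate with probability
#' `effect_predicate` and a signal source with probability
#' `effect_provenance` (background labels otherwise); negative combinations
#' always draw background labels. At `effect = 0` the two classes are
#' exchangeable.
#'
#' @param n_proteins number of proteins in the background graph
#' @param n_predicates,n_sources vocabulary sizes (defaults 45 and 25)
#' @param edge_density expected edges per protein (mean degree is twice this)
#' @param n_pos,n_neg number of positive / negative combinations
#' @param dt_size_max,dp_size_max caps on sampled set sizes (defaults 51 and
#'   273, the published maxima)
#' @param n_signal_predicates,n_signal_sources how many labels carry signal
#' @param effect probability that a planted positive-path triple carries a
#'   signal label; `effect_predicate`/`effect_provenance` override it per
#'   kind
#' @param effect_predicate,effect_provenance per-kind signal probabilities
#' @param scenario_mix named numeric proportions for planted paths
#'   (`overlap`, `direct`, `indirect`)
#' @param paths_per_combo planted paths per combination
#' @param fixed_plant_source optional source label stamped on *every*
#'   planted triple of both classes (overriding `effect_provenance`);
#'   concentrates all planted structure in one source so that
#'   leave-one-source-out ablation removes it symmetrically
#' @param degree_dist `"heavy_tail"` (default) or `"uniform"` background
#'   degree profile
#' @param seed integer seed
#' @return List of class `kg_synth_config`.
#' @export
synth_config <- function(n_proteins = 1000L, n_predicates = 45L,
                         n_sources = 25L, edge_density = 4,
                         n_pos = 100L, n_neg = 300L,
                         dt_size_max = 51L, dp_size_max = 273L,
                         n_signal_predicates = 3L, n_signal_sources = 2L,
                         effect = 0.8, effect_predicate = NULL,
                         effect_provenance = NULL,
                         scenario_mix = c(overlap = 0.1, direct = 0.4,
                                          indirect = 0.5),
                         paths_per_combo = 3L,
                         fixed_plant_source = NULL,
                         degree_dist = c("heavy_tail", "uniform"),
                         seed = 1L) {
  stopifnot(n_proteins >= 10L, n_predicates >= n_signal_predicates,
            n_sources >= n_signal_sources, edge_density >= 0,
            n_pos >= 1L, n_neg >= 1L, paths_per_combo >= 0L)
  if (is.null(effect_predicate)) effect_predicate <- effect
  if (is.null(effect_provenance)) effect_provenance <- effect
  stopifnot(effect >= 0, effect <= 1, effect_predicate >= 0,
            effect_predicate <= 1, effect_provenance >= 0,
            effect_provenance <= 1)
  scenario_mix <- scenario_mix / sum(scenario_mix)
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_predicates = as.integer(n_predicates),
    n_sources = as.integer(n_sources),
    edge_density = edge_density,
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    dt_size_max = as.integer(dt_size_max),
    dp_size_max = as.integer(dp_size_max),
    n_signal_predicates = as.integer(n_signal_predicates),
    n_signal_sources = as.integer(n_signal_sources),
    effect_predicate = effect_predicate,
    effect_provenance = effect_provenance,
    scenario_mix = scenario_mix,
    paths_per_combo = as.integer(paths_per_combo),
    fixed_plant_source = fixed_plant_source,
    degree_dist = match.arg(degree_dist),
    seed = as.integer(seed)), class = "kg_synth_config")
}

.protein_names <- function(n) sprintf("P%04d", seq_len(n))
.predicate_names <- function(n) sprintf("pred%02d", seq_len(n))
.source_names <- function(n) sprintf("SRC%02d", seq_len(n))

.signal_predicates <- function(config)
  .predicate_names(config$n_predicates)[seq_len(config$n_signal_predicates)]
.signal_sources <- function(config)
  .source_names(config$n_sources)[seq_len(config$n_signal_sources)]

# Zipf-like background sampling over the non-signal labels: a few labels are
# common, most are rare, as in real source/predicate frequency tables.
.background_sampler <- function(labels) {
  w <- 1 / seq_along(labels)
  function(n) sample(labels, n, replace = TRUE, prob = w)
}

#' Generate a random background knowledge graph
#'
#' Draws a simple undirected graph with `n_proteins * edge_density` edges via
#' an expected-degree (fitness) model — heavy-tailed fitness weights by
#' default — then decorates each edge with 1-3 predicates drawn from a
#' Zipf-like background distribution over the non-signal vocabulary, each
#' triple attested by 1-3 background sources. Subject/object orientation is
#' randomized (path extraction ignores it). Signal labels are reserved for
#' [generate_reference()] planting so the background carries no class
#' information. A small fraction of proteins receive self-relationship
#' triples.
#'
#' @param config a [synth_config()]
#' @return A [kg_graph()] whose vocabularies are the full configured label
#'   sets (signal labels included even when absent from background triples).
#' @export
generate_graph <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  proteins <- .protein_names(n)
  m <- as.integer(round(n * config$edge_density))
  max_edges <- n * (n - 1) / 2
  if (m > max_edges)
    stop("edge_density ", config$edge_density, " infeasible for ",
         n, " proteins")
  preds <- .predicate_names(config$n_predicates)
  srcs <- .source_names(config$n_sources)
  bg_preds <- setdiff(preds, .signal_predicates(config))
  bg_srcs <- setdiff(srcs, .signal_sources(config))
  sample_pred <- .background_sampler(bg_preds)
  sample_src <- .background_sampler(bg_srcs)

  triples <- data.frame(subject = character(), predicate = character(),
                        object = character(), provenance = character())
  if (m > 0L) {
    w <- if (config$degree_dist == "heavy_tail")
      (1 - stats::runif(n)) ^ (-1 / 1.5) else rep(1, n)  # Pareto tail ~2.5
    g <- igraph::sample_fitness(m, fitness.out = w, loops = FALSE,
                                multiple = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    a <- proteins[el[, 1L]]; b <- proteins[el[, 2L]]
    flip <- stats::runif(nrow(el)) < 0.5
    subj <- ifelse(flip, b, a); obj <- ifelse(flip, a, b)
    n_pred <- sample(1:3, nrow(el), replace = TRUE, prob = c(0.6, 0.3, 0.1))
    edge_of <- rep(seq_len(nrow(el)), n_pred)
    pred <- sample_pred(length(edge_of))
    keep <- !duplicated(paste(edge_of, pred))  # one triple per (edge, predicate)
    edge_of <- edge_of[keep]; pred <- pred[keep]
    n_src <- sample(1:3, length(edge_of), replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
    prov <- sample_src(length(edge_of))
    i2 <- which(n_src >= 2L)
    prov[i2] <- paste(prov[i2], sample_src(length(i2)), sep = ";")
    i3 <- which(n_src == 3L)
    prov[i3] <- paste(prov[i3], sample_src(length(i3)), sep = ";")
    triples <- data.frame(subject = subj[edge_of], predicate = pred,
                          object = obj[edge_of], provenance = prov,
                          stringsAsFactors = FALSE)
    # sparse self-relationships (e.g. homodimerization)
    n_self <- max(0L, round(0.01 * n))
    if (n_self > 0L) {
      selfp <- sample(proteins, n_self)
      triples <- rbind(triples, data.frame(
        subject = selfp, predicate = sample_pred(n_self), object = selfp,
        provenance = sample_src(n_self), stringsAsFactors = FALSE))
    }
  }
  kg_graph(triples, proteins = proteins, predicates = preds, sources = srcs)
}

# set-size sampler emulating the published medians (drug-target sets: median
# 2; disease-protein sets: median ~5) with long right tails
.sample_set_size <- function(n, role, cap) {
  mu <- if (role == "dt") 1.6 else 5.2
  size <- if (role == "dt") 1.2 else 0.9
  pmin(1L + stats::rnbinom(n, mu = mu, size = size), cap)
}

#' Generate a labelled synthetic reference set with planted signal
#'
#' Samples `n_pos + n_neg` combinations whose set sizes follow the configured
#' distributions, then plants `paths_per_combo` paths per combination with
#' scenario drawn from `scenario_mix`; planting is structurally identical for
#' both classes, but the predicate/provenance labels of planted triples carry
#' the designated signal labels with the configured per-kind probabilities
#' for positives only. The returned graph extends the input graph with the
#' planted triples.
#'
#' @param graph a background [kg_graph()] from [generate_graph()]
#' @param config the same [synth_config()]
#' @return List of class `kg_synth_bundle`: `graph` (augmented),
#'   `combos`, `truth` (signal labels, the feature ids they can light up,
#'   effect sizes), and `config`.
#' @export
generate_reference <- function(graph, config) {
  set.seed(config$seed + 1L)
  if (!is.null(config$fixed_plant_source) &&
      !config$fixed_plant_source %in% graph$sources)
    stop("fixed_plant_source not in the graph's source vocabulary")
  proteins <- graph$proteins
  sig_preds <- .signal_predicates(config)
  sig_srcs <- .signal_sources(config)
  bg_preds <- setdiff(graph$predicates, sig_preds)
  bg_srcs <- setdiff(graph$sources, sig_srcs)
  sample_pred <- .background_sampler(bg_preds)
  sample_src <- .background_sampler(bg_srcs)
  n_total <- config$n_pos + config$n_neg
  labels <- rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
  dt_sizes <- .sample_set_size(n_total, "dt",
                               min(config$dt_size_max, length(proteins) %/% 4L))
  dp_sizes <- .sample_set_size(n_total, "dp",
                               min(config$dp_size_max, length(proteins) %/% 4L))
  scen_names <- names(config$scenario_mix)
  combos <- vector("list", n_total)
  new_rows <- list()
  plant_triple <- function(s, o, positive) {
    pred <- if (positive && stats::runif(1) < config$effect_predicate)
      sample(sig_preds, 1L) else sample_pred(1L)
    src <- if (!is.null(config$fixed_plant_source)) config$fixed_plant_source
      else if (positive && stats::runif(1) < config$effect_provenance)
        sample(sig_srcs, 1L) else sample_src(1L)
    new_rows[[length(new_rows) + 1L]] <<- data.frame(
      subject = s, predicate = pred, object = o, provenance = src,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_total)) {
    members <- sample(proteins, dt_sizes[i] + dp_sizes[i])
    dt <- members[seq_len(dt_sizes[i])]
    dp <- members[-seq_len(dt_sizes[i])]
    positive <- labels[i] == "positive"
    for (j in seq_len(config$paths_per_combo)) {
      scen <- sample(scen_names, 1L, prob = config$scenario_mix)
      if (scen == "overlap") {
        shared <- sample(dt, 1L)
        dp <- unique(c(dp, shared))
        if (stats::runif(1) < 0.5) plant_triple(shared, shared, positive)
      } else if (scen == "direct") {
        plant_triple(sample(dt, 1L), sample(dp, 1L), positive)
      } else {
        ip <- sample(setdiff(proteins, c(dt, dp)), 1L)
        plant_triple(sample(dt, 1L), ip, positive)
        plant_triple(ip, sample(dp, 1L), positive)
      }
    }
    combos[[i]] <- combination(sprintf("c%04d", i), dt, dp, labels[i])
  }
  all_triples <- graph$triples
  all_triples$provenance <- vapply(all_triples$provenance, paste, "",
                                   collapse = ";")
  if (length(new_rows))
    all_triples <- rbind(all_triples, do.call(rbind, new_rows))
  aug <- kg_graph(all_triples, proteins = proteins,
                  predicates = graph$predicates, sources = graph$sources)
  slot_for <- c(overlap = "SELF", direct = "DIRECT")
  informative <- character()
  for (scen in scen_names[config$scenario_mix > 0]) {
    slots <- if (scen == "indirect") c("DTIP", "IPDP") else slot_for[[scen]]
    for (sl in slots)
      informative <- c(informative,
                       paste(sl, "predicate", sig_preds, sep = ":"),
                       paste(sl, "provenance", sig_srcs, sep = ":"))
  }
  structure(list(
    graph = aug, combos = combos,
    truth = list(signal_predicates = sig_preds, signal_sources = sig_srcs,
                 informative_features = unique(informative),
                 effect_predicate = config$effect_predicate,
                 effect_provenance = config$effect_provenance),
    config = config), class = "kg_synth_bundle")
}

#' Hand-built fixture with one instance of each path scenario
#'
#' An eight-protein graph containing exactly one overlap combination (shared
#' protein with a homodimerization self-relationship), one direct
#' combination (a single binding triple) and one indirect combination (a
#' two-step path through one intermediate), plus background proteins. Used
#' by exact unit tests across modules.
#'
#' @return A `kg_synth_bundle` with `graph`, three `combos` (ids
#'   `fig1a`, `fig1b`, `fig1c`) and a `truth` record of the constructed
#'   paths.
#' @export
fig1_fixture <- function() {
  triples <- data.frame(
    subject = c("P1", "P2", "P4", "P5", "P7"),
    predicate = c("homodimerizes", "binds", "activates", "inhibits",
                  "coexists with"),
    object = c("P1", "P3", "P5", "P6", "P8"),
    provenance = c("Reactome", "CTD", "SemMedDB", "CTD;SemMedDB", "TextMine"),
    stringsAsFactors = FALSE)
  graph <- kg_graph(triples)
  combos <- list(
    combination("fig1a", "P1", "P1", "positive"),
    combination("fig1b", "P2", "P3", "positive"),
    combination("fig1c", "P4", "P6", "positive"))
  structure(list(
    graph = graph, combos = combos,
    truth = list(overlap_protein = "P1", direct_pair = c("P2", "P3"),
                 indirect_path = c("P4", "P5", "P6")),
    config = NULL), class = "kg_synth_bundle")
}

#' @export
print.kg_synth_bundle <- function(x, ...) {
  cat(sprintf("<kg_synth_bundle> %d combos on a graph with %d proteins / %d triples\n",
              length(x$combos), length(x$graph$proteins),
              nrow(x$graph$triples)))
  invisible(x)
}
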