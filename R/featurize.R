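.SLOT_ORDER <- c("OVERLAP_FLAG", "COOC_DIRECT", "COOC_INDIRECT",
                 "SELF", "DIRECT", "DTIP", "IPDP")
.KIND_ORDER <- c("flag", "predicate", "provenance")

.feature_rows <- function(slot, kind, values) {
  if (!length(values)) return(NULL)
  data.frame(id = paste(slot, kind, values, sep = ":"),
             slot = slot, kind = kind, value = values,
             stringsAsFactors = FALSE)
}

#' Build the ordered binary feature space for a graph
#'
#' Features are presence/absence indicators over the three path scenarios.
#' Five variants are supported:
#'
#' * `"baseline"` — three co-occurrence flags only (`overlap`,
#'   `has_direct_relationship`, `has_indirect_relationship`), carrying no
#'   predicate or provenance information;
#' * `"full"` — the overlap flag plus, for each of the four triple slots
#'   (SELF for self-relationships of overlapping proteins, DIRECT, and the
#'   two indirect steps DTIP and IPDP), one indicator per predicate type and
#'   one per provenance source: `1 + 4 * (P + S)` features for `P` predicate
#'   types and `S` sources (281 at the reference scale of 45 and 25);
#' * `"predicate"` / `"provenance"` — the overlap flag plus only the
#'   predicate (resp. provenance) indicators of the four slots;
#' * `"indirect_only"` — the DTIP and IPDP indicators only, with every
#'   overlap, SELF and DIRECT feature removed; quantifies how much of the
#'   signal survives without any proximity between the two sets.
#'
#' Ordering is deterministic: slot, then kind (flag, predicate, provenance),
#' then lexicographic value.
#'
#' @param graph a [kg_graph()] supplying the predicate and source vocabularies
#' @param variant one of `"baseline"`, `"predicate"`, `"provenance"`,
#'   `"full"`, `"indirect_only"`
#' @return A data.frame of class `kg_feature_spec` with columns `id`, `slot`,
#'   `kind`, `value` and attribute `variant`.
#' @export
build_feature_space <- function(graph, variant = c("full", "baseline",
                                                   "predicate", "provenance",
                                                   "indirect_only")) {
  variant <- match.arg(tolower(variant[1L]), c("full", "baseline", "predicate",
                                               "provenance", "indirect_only"))
  preds <- sort(graph$predicates)
  srcs <- sort(graph$sources)
  overlap <- .feature_rows("OVERLAP_FLAG", "flag", "overlap")
  rows <- switch(variant,
    baseline = rbind(
      overlap,
      .feature_rows("COOC_DIRECT", "flag", "has_direct_relationship"),
      .feature_rows("COOC_INDIRECT", "flag", "has_indirect_relationship")),
    full = ,
    predicate = ,
    provenance = {
      slots <- c("SELF", "DIRECT", "DTIP", "IPDP")
      kinds <- switch(variant, full = c("predicate", "provenance"),
                      predicate = "predicate", provenance = "provenance")
      parts <- list(overlap)
      for (slot in slots) for (kind in kinds)
        parts[[length(parts) + 1L]] <- .feature_rows(
          slot, kind, if (kind == "predicate") preds else srcs)
      do.call(rbind, parts)
    },
    indirect_only = {
      parts <- list()
      for (slot in c("DTIP", "IPDP")) for (kind in c("predicate", "provenance"))
        parts[[length(parts) + 1L]] <- .feature_rows(
          slot, kind, if (kind == "predicate") preds else srcs)
      do.call(rbind, parts)
    })
  rows <- rows[order(match(rows$slot, .SLOT_ORDER),
                     match(rows$kind, .KIND_ORDER), rows$value), ]
  rownames(rows) <- NULL
  attr(rows, "variant") <- variant
  class(rows) <- c("kg_feature_spec", "data.frame")
  rows
}

# slot -> (predicates, sources) label sets realized by a combination's paths
.slot_label_sets <- function(combo, graph) {
  ov <- find_overlap(combo, graph)
  di <- find_direct(combo, graph)
  ind <- find_indirect(combo, graph)
  labels_of <- function(idx) {
    idx <- unique(idx)
    list(predicates = unique(graph$triples$predicate[idx]),
         sources = unique(unlist(graph$triples$provenance[idx])))
  }
  list(
    overlap = length(ov) > 0L,
    direct = length(di) > 0L,
    indirect = length(ind) > 0L,
    SELF = labels_of(unlist(lapply(ov, `[[`, "triples"))),
    DIRECT = labels_of(unlist(lapply(di, `[[`, "triples"))),
    DTIP = labels_of(unlist(lapply(ind, `[[`, "dtip"))),
    IPDP = labels_of(unlist(lapply(ind, `[[`, "ipdp"))))
}

#' Extract one combination's binary feature vector
#'
#' A predicate (provenance) feature is set to 1 exactly when its label occurs
#' on at least one triple of the corresponding slot among the combination's
#' extracted paths; the flags are set when the respective scenario occurs at
#' all. A combination with no paths yields the all-zero vector.
#'
#' @param combo a [combination()]
#' @param graph the [kg_graph()] the spec was built from (vocabularies must
#'   cover the spec's labels)
#' @param spec a [build_feature_space()] result
#' @return Named integer 0/1 vector aligned with `spec$id`.
#' @export
extract_features <- function(combo, graph, spec) {
  vals <- spec$value[spec$kind == "predicate"]
  if (length(setdiff(vals, graph$predicates)))
    stop("feature spec predicates missing from graph vocabulary")
  vals <- spec$value[spec$kind == "provenance"]
  if (length(setdiff(vals, graph$sources)))
    stop("feature spec sources missing from graph vocabulary")

  sets <- .slot_label_sets(combo, graph)
  bits <- integer(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    slot <- spec$slot[i]
    bits[i] <- switch(slot,
      OVERLAP_FLAG = as.integer(sets$overlap),
      COOC_DIRECT = as.integer(sets$direct),
      COOC_INDIRECT = as.integer(sets$indirect),
      as.integer(spec$value[i] %in%
        (if (spec$kind[i] == "predicate") sets[[slot]]$predicates
         else sets[[slot]]$sources)))
  }
  names(bits) <- spec$id
  bits
}

#' Extract the feature matrix for a list of combinations
#'
#' @param combos list of [combination()] objects
#' @inheritParams extract_features
#' @return Integer 0/1 matrix, rows named by combo id, columns by feature id,
#'   with attribute `labels`.
#' @export
extract_feature_matrix <- function(combos, graph, spec) {
  mat <- t(vapply(combos, extract_features, integer(nrow(spec)),
                  graph = graph, spec = spec))
  if (nrow(spec) == 1L) mat <- matrix(mat, ncol = 1L)
  rownames(mat) <- combo_ids(combos)
  colnames(mat) <- spec$id
  attr(mat, "labels") <- combo_labels(combos)
  mat
}

#' Remove everything a single knowledge source exclusively contributes
#'
#' Emulates leaving one source out of the graph: provenance features of the
#' excluded source are dropped, triples attested *only* by that source are
#' deleted, any predicate feature left without a supporting triple anywhere
#' in the graph is dropped, and the remaining columns are re-extracted on the
#' reduced graph. Triples the source shares with other sources survive, so a
#' redundantly-attested relationship keeps its predicate features.
#'
#' @param spec a [build_feature_space()] result
#' @param combos list of [combination()] objects to re-extract
#' @param graph the [kg_graph()] the spec was built from
#' @param excluded_source a source label from `graph$sources`
#' @return List with `spec` (reduced), `features` (re-extracted matrix) and
#'   `graph` (the source-ablated graph, vocabularies unchanged).
#' @export
restrict_to_sources <- function(spec, combos, graph, excluded_source) {
  if (!excluded_source %in% graph$sources)
    stop("unknown source: ", excluded_source)
  sole <- vapply(graph$triples$provenance,
                 function(p) identical(p, excluded_source), TRUE)
  reduced <- kg_graph(graph$triples[!sole, , drop = FALSE],
                      proteins = graph$proteins,
                      predicates = graph$predicates, sources = graph$sources)
  surviving_preds <- unique(reduced$triples$predicate)
  drop <- (spec$kind == "provenance" & spec$value == excluded_source) |
    (spec$kind == "predicate" & !spec$value %in% surviving_preds)
  spec2 <- spec[!drop, , drop = FALSE]
  rownames(spec2) <- NULL
  attr(spec2, "variant") <- attr(spec, "variant")
  class(spec2) <- c("kg_feature_spec", "data.frame")
  list(spec = spec2,
       features = extract_feature_matrix(combos, reduced, spec2),
       graph = reduced)
}
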