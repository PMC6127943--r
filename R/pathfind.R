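#' Path extraction between drug targets and disease proteins
#'
#' Three scenarios connect a drug-target set to a disease-protein set, and
#' only paths of length at most two (one intermediate protein) are
#' considered — longer paths add little coverage and no performance:
#'
#' * **overlap** — a protein is simultaneously a drug target and a disease
#'   protein; it may additionally have a self-relationship (e.g.
#'   homodimerization), but need not;
#' * **direct** — a drug target and a distinct disease protein are joined by
#'   at least one triple, in either orientation;
#' * **indirect** — a drug target and a distinct disease protein are joined
#'   through one intermediate protein, giving a two-step path whose steps are
#'   featurized separately (drug target to intermediate, "DTIP", and
#'   intermediate to disease protein, "IPDP").
#'
#' Each record is a list with elements `scenario`, `dt`, `dp`, `ip` (`NA`
#' except for indirect records) and triple indices into `graph$triples`:
#' `triples` for overlap/direct records, `dtip`/`ipdp` step bags for indirect
#' records. Matching ignores subject/object orientation.
#'
#' @param combo a [combination()]
#' @param graph a [kg_graph()]
#' @return A list of path records (possibly empty).
#' @name pathfind
NULL

#' @describeIn pathfind one record per protein shared between the two sets;
#'   `triples` holds the protein's self-relationship triples and may be empty.
#' @export
find_overlap <- function(combo, graph) {
  shared <- intersect(combo$drug_targets, combo$disease_proteins)
  lapply(sort(shared), function(p) {
    list(scenario = "OVERLAP", dt = p, dp = p, ip = NA_character_,
         triples = triples_between(graph, p, p))
  })
}

#' @describeIn pathfind one record per (drug target, disease protein) pair,
#'   with the two proteins distinct, joined by at least one triple.
#' @export
find_direct <- function(combo, graph) {
  out <- list()
  for (dt in sort(combo$drug_targets)) {
    for (dp in sort(combo$disease_proteins)) {
      if (dt == dp) next
      idx <- triples_between(graph, dt, dp)
      if (length(idx))
        out[[length(out) + 1L]] <- list(scenario = "DIRECT", dt = dt, dp = dp,
                                        ip = NA_character_, triples = idx)
    }
  }
  out
}

#' @describeIn pathfind one record per (drug target, intermediate, disease
#'   protein) two-step path; the intermediate differs from both endpoints but
#'   may itself belong to either protein set.
#' @export
find_indirect <- function(combo, graph) {
  out <- list()
  for (dt in sort(combo$drug_targets)) {
    nb_dt <- graph_neighbors(graph, dt)
    if (!length(nb_dt)) next
    for (dp in sort(combo$disease_proteins)) {
      if (dt == dp) next
      ips <- setdiff(intersect(nb_dt, graph_neighbors(graph, dp)), c(dt, dp))
      for (ip in ips)
        out[[length(out) + 1L]] <- list(
          scenario = "INDIRECT", dt = dt, dp = dp, ip = ip,
          dtip = triples_between(graph, dt, ip),
          ipdp = triples_between(graph, ip, dp))
    }
  }
  out
}

#' Does a disease protein have any qualifying path to the drug targets?
#'
#' A disease protein is usable for feature extraction when it overlaps a drug
#' target or is connected to one by a direct or two-step indirect path; the
#' fraction of disease proteins failing this test is worth reporting for any
#' reference set.
#'
#' @param dp a disease-protein id belonging to `combo$disease_proteins`
#' @param combo a [combination()]
#' @param graph a [kg_graph()]
#' @return Logical scalar.
#' @export
has_qualifying_path <- function(dp, combo, graph) {
  if (dp %in% combo$drug_targets) return(TRUE)
  nb_dp <- graph_neighbors(graph, dp)
  for (dt in combo$drug_targets) {
    if (dt == dp) next
    if (length(triples_between(graph, dt, dp))) return(TRUE)
    if (length(setdiff(intersect(nb_dp, graph_neighbors(graph, dt)),
                       c(dt, dp)))) return(TRUE)
  }
  FALSE
}

#' Flatten path records to a table
#'
#' One row per (triple, step) for export or inspection: columns `scenario`,
#' `dt`, `ip`, `dp`, `step` (SELF, DIRECT, DTIP or IPDP), `predicate`,
#' `source`.
#'
#' @param records list of path records from the `find_*` functions
#' @param graph the [kg_graph()] the records refer to
#' @return A data.frame.
#' @export
paths_as_table <- function(records, graph) {
  rows <- list()
  add <- function(rec, step, idx) {
    for (i in idx) {
      tr <- graph$triples[i, ]
      for (src in tr$provenance[[1L]])
        rows[[length(rows) + 1L]] <<- data.frame(
          scenario = rec$scenario, dt = rec$dt, ip = rec$ip, dp = rec$dp,
          step = step, predicate = tr$predicate, source = src,
          stringsAsFactors = FALSE)
    }
  }
  for (rec in records) {
    if (rec$scenario == "OVERLAP") add(rec, "SELF", rec$triples)
    else if (rec$scenario == "DIRECT") add(rec, "DIRECT", rec$triples)
    else { add(rec, "DTIP", rec$dtip); add(rec, "IPDP", rec$ipdp) }
  }
  if (!length(rows))
    return(data.frame(scenario = character(), dt = character(),
                      ip = character(), dp = character(), step = character(),
                      predicate = character(), source = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
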