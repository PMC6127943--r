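#' Construct a protein knowledge graph from a triple table
#'
#' A knowledge graph stores subject-predicate-object triples between proteins,
#' each carrying a non-empty set of provenance sources (the databases or
#' literature extracts attesting the relationship). All triples sharing the
#' same (subject, predicate, object) key are merged into one triple whose
#' provenance is the union of the individual provenance sets. The "edge"
#' between an unordered protein pair is the set of all triples connecting the
#' pair, in either orientation; connectivity is treated as undirected
#' throughout, since many protein-protein predicates (complex formation,
#' binding) are symmetric and path semantics never depend on orientation.
#'
#' @param triples data.frame with columns `subject`, `predicate`, `object`
#'   (character) and `provenance` (either a character vector of
#'   semicolon-joined source labels or a list of character vectors).
#' @param proteins optional character vector of protein ids to include even
#'   when isolated (no incident triples).
#' @param predicates,sources optional vocabulary supersets; the observed
#'   predicates/sources are always included.
#' @return An object of class `kg_graph`: a list with elements `proteins`,
#'   `triples` (merged triple table with list-column `provenance`),
#'   `predicates`, `sources`, plus internal pair/adjacency indexes.
#' @examples
#' g <- kg_graph(data.frame(subject = "A", predicate = "binds",
#'                          object = "B", provenance = "S1"))
#' g$proteins
#' @export
kg_graph <- function(triples, proteins = NULL, predicates = NULL,
                     sources = NULL) {
  stopifnot(is.data.frame(triples))
  if (nrow(triples) == 0L) {
    triples <- data.frame(subject = character(), predicate = character(),
                          object = character())
    triples$provenance <- list()
  }
  req <- c("subject", "predicate", "object", "provenance")
  missing_cols <- setdiff(req, names(triples))
  if (length(missing_cols) && nrow(triples) > 0L)
    stop("triple table lacks column(s): ", paste(missing_cols, collapse = ", "))

  prov <- triples$provenance
  if (!is.list(prov)) prov <- strsplit(as.character(prov), ";", fixed = TRUE)
  prov <- lapply(prov, function(p) {
    p <- unique(p[nzchar(p)])
    if (length(p) == 0L) stop("triple with empty provenance set")
    sort(p)
  })

  subj <- as.character(triples$subject)
  obj <- as.character(triples$object)
  pred <- as.character(triples$predicate)
  ids <- c(subj, obj)
  if (any(!nzchar(ids)) || any(grepl("[[:space:]|;]", ids)))
    stop("protein ids must be non-empty and free of whitespace, '|' and ';'")

  # merge duplicate (s,p,o) records, unioning provenance
  key <- paste(subj, pred, obj, sep = "\t")
  ord <- order(key)
  keep <- !duplicated(key)
  merged_prov <- lapply(split(prov, key), function(ps) sort(unique(unlist(ps))))
  tr <- data.frame(subject = subj[keep], predicate = pred[keep],
                   object = obj[keep], stringsAsFactors = FALSE)
  tr$provenance <- merged_prov[key[keep]]
  names(tr$provenance) <- NULL
  rownames(tr) <- NULL

  g <- list(
    proteins = sort(unique(c(tr$subject, tr$object, proteins))),
    triples = tr,
    predicates = sort(unique(c(tr$predicate, predicates))),
    sources = sort(unique(c(unlist(tr$provenance), sources)))
  )
  g$pair_index <- .build_pair_index(tr)
  g$adjacency <- .build_adjacency(tr)
  g$cache <- new.env(parent = emptyenv())
  class(g) <- "kg_graph"
  g
}

.pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}

.build_pair_index <- function(tr) {
  env <- new.env(parent = emptyenv(), size = max(16L, nrow(tr)))
  if (nrow(tr)) {
    keys <- .pair_key(tr$subject, tr$object)
    by_key <- split(seq_len(nrow(tr)), keys)
    for (k in names(by_key)) assign(k, by_key[[k]], envir = env)
  }
  env
}

.build_adjacency <- function(tr) {
  env <- new.env(parent = emptyenv())
  if (nrow(tr)) {
    nb <- split(c(tr$object, tr$subject), c(tr$subject, tr$object))
    for (p in names(nb)) assign(p, sort(unique(nb[[p]])), envir = env)
  }
  env
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf(
    "<kg_graph> %d proteins, %d triples, %d predicate types, %d sources\n",
    length(x$proteins), nrow(x$triples), length(x$predicates),
    length(x$sources)))
  invisible(x)
}

#' All triples connecting two proteins (either orientation)
#'
#' With `a == b`, returns the protein's self-relationship triples.
#'
#' @param graph a [kg_graph()]
#' @param a,b protein ids
#' @return Integer row indices into `graph$triples` (possibly empty).
#' @export
triples_between <- function(graph, a, b) {
  idx <- get0(.pair_key(a, b), envir = graph$pair_index, inherits = FALSE)
  if (is.null(idx)) integer() else idx
}

#' Neighbours of a protein
#'
#' Proteins connected to `p` by at least one triple in either orientation;
#' `p` itself appears when it has a self-relationship. Unknown proteins have
#' no neighbours.
#'
#' @param graph a [kg_graph()]
#' @param p protein id
#' @return Character vector of protein ids.
#' @export
graph_neighbors <- function(graph, p) {
  nb <- get0(p, envir = graph$adjacency, inherits = FALSE)
  if (is.null(nb)) character() else nb
}

#' Read a triple store from a tab-separated file
#'
#' Expected dialect: UTF-8, one triple per line with four tab-separated
#' fields `subject`, `predicate`, `object`, `provenance` (semicolon-joined
#' source labels); `#` starts a comment line; blank lines are ignored.
#' Duplicate (subject, predicate, object) lines merge their provenance sets.
#'
#' @param path file path
#' @return A [kg_graph()].
#' @export
read_triples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  # strsplit drops trailing empty fields; pad so an empty provenance column
  # is reported as such, not as a malformed line
  parts <- strsplit(paste0(lines, "\t\v"), "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 5L)
  if (length(bad))
    stop(sprintf("malformed triple line %d: expected >= 4 tab-separated fields",
                 lineno[bad[1L]]))
  prov <- vapply(parts, `[[`, "", 4L)
  empty <- which(!nzchar(gsub(";", "", prov)))
  if (length(empty))
    stop(sprintf("empty provenance field at line %d", lineno[empty[1L]]))
  kg_graph(data.frame(
    subject = vapply(parts, `[[`, "", 1L),
    predicate = vapply(parts, `[[`, "", 2L),
    object = vapply(parts, `[[`, "", 3L),
    provenance = prov,
    stringsAsFactors = FALSE))
}

#' Write a knowledge graph as a tab-separated triple store
#'
#' Inverse of [read_triples()]; the round trip preserves protein, triple and
#' vocabulary counts. Isolated proteins are recorded in a header comment and
#' are not recoverable from the triple lines alone.
#'
#' @param graph a [kg_graph()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_triples <- function(graph, path) {
  tr <- graph$triples
  lines <- c(
    "# subject\tpredicate\tobject\tprovenance",
    paste(tr$subject, tr$predicate, tr$object,
          vapply(tr$provenance, paste, "", collapse = ";"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
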