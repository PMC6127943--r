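#' A drug-disease combination
#'
#' The unit of classification: a set of drug-target proteins (representing
#' one or more drugs), a set of disease proteins (representing one or more
#' diseases) and a label. Negative combinations are typically random
#' pairings of the positive sets' components.
#'
#' @param combo_id identifier string
#' @param drug_targets character vector of protein ids (non-empty)
#' @param disease_proteins character vector of protein ids (non-empty)
#' @param label one of `"positive"`, `"negative"`, `"unlabeled"`
#' @return An object of class `kg_combination`.
#' @export
combination <- function(combo_id, drug_targets, disease_proteins,
                        label = "unlabeled") {
  drug_targets <- unique(as.character(drug_targets))
  disease_proteins <- unique(as.character(disease_proteins))
  if (length(drug_targets) == 0L || any(!nzchar(drug_targets)))
    stop("combination ", combo_id, ": drug-target set must be non-empty")
  if (length(disease_proteins) == 0L || any(!nzchar(disease_proteins)))
    stop("combination ", combo_id, ": disease-protein set must be non-empty")
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  structure(list(combo_id = as.character(combo_id),
                 drug_targets = drug_targets,
                 disease_proteins = disease_proteins,
                 label = label),
            class = "kg_combination")
}

#' @export
print.kg_combination <- function(x, ...) {
  cat(sprintf("<kg_combination> %s [%s]: %d drug targets vs %d disease proteins\n",
              x$combo_id, x$label, length(x$drug_targets),
              length(x$disease_proteins)))
  invisible(x)
}

#' Labels / ids of a combination list
#'
#' @param combos list of [combination()] objects
#' @return Character vector.
#' @export
combo_labels <- function(combos) vapply(combos, `[[`, "", "label")

#' @rdname combo_labels
#' @export
combo_ids <- function(combos) vapply(combos, `[[`, "", "combo_id")

#' Read a reference set of labelled drug-disease combinations
#'
#' Expected dialect: tab-separated columns `combo_id`, drug targets
#' (pipe-joined protein ids), disease proteins (pipe-joined), `label`;
#' `#` comment lines allowed. Proteins absent from the graph are retained in
#' the sets — combinations are only excluded later, during analysis, when no
#' qualifying path exists — but flagged in the attached load report.
#'
#' @param path file path
#' @param graph a [kg_graph()] used to flag unknown proteins
#' @return List of [combination()] objects with attribute `"load_report"`, a
#'   data.frame of (combo_id, protein, role) rows for proteins not present in
#'   the graph.
#' @export
read_reference_set <- function(path, graph) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad))
    stop(sprintf("malformed reference-set line %d: expected 4 tab-separated fields",
                 lineno[bad[1L]]))
  combos <- vector("list", length(parts))
  report <- list()
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (!f[[4L]] %in% c("positive", "negative", "unlabeled"))
      stop(sprintf("unknown label '%s' at line %d", f[[4L]], lineno[i]))
    dt <- strsplit(f[[2L]], "|", fixed = TRUE)[[1L]]
    dp <- strsplit(f[[3L]], "|", fixed = TRUE)[[1L]]
    combos[[i]] <- combination(f[[1L]], dt, dp, f[[4L]])
    unknown_dt <- setdiff(combos[[i]]$drug_targets, graph$proteins)
    unknown_dp <- setdiff(combos[[i]]$disease_proteins, graph$proteins)
    if (length(unknown_dt) || length(unknown_dp))
      report[[length(report) + 1L]] <- data.frame(
        combo_id = f[[1L]],
        protein = c(unknown_dt, unknown_dp),
        role = rep(c("drug_target", "disease_protein"),
                   c(length(unknown_dt), length(unknown_dp))),
        stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(combo_id = character(), protein = character(),
               role = character(), stringsAsFactors = FALSE)
  attr(combos, "load_report") <- report
  combos
}

#' Write a reference set in the tab-separated dialect of [read_reference_set()]
#'
#' @param combos list of [combination()] objects
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(combos, path) {
  lines <- c("# combo_id\tdrug_targets\tdisease_proteins\tlabel",
             vapply(combos, function(cb) {
               paste(cb$combo_id,
                     paste(cb$drug_targets, collapse = "|"),
                     paste(cb$disease_proteins, collapse = "|"),
                     cb$label, sep = "\t")
             }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a binary feature matrix as wide TSV
#'
#' Columns: `combo_id`, `label`, then one 0/1 column per feature id of the
#' spec. Round-trips losslessly through [read_feature_matrix()].
#'
#' @param combos list of [combination()] objects, aligned with matrix rows
#' @param spec a feature spec from [build_feature_space()]
#' @param features 0/1 matrix, rows = combinations, columns = spec features
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(combos, spec, features, path) {
  features <- as.matrix(features)
  if (nrow(features) != length(combos))
    stop("feature matrix rows (", nrow(features),
         ") do not match number of combinations (", length(combos), ")")
  if (ncol(features) != nrow(spec))
    stop("feature matrix columns (", ncol(features),
         ") do not match feature spec length (", nrow(spec), ")")
  df <- data.frame(combo_id = combo_ids(combos), label = combo_labels(combos),
                   stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.data.frame(features)
  names(mat) <- spec$id
  utils::write.table(cbind(df, mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path file path
#' @return List with `features` (0/1 matrix with combo_id rownames and
#'   feature-id colnames) and `labels` (character vector).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), c("combo_id", "label")),
                      drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$combo_id
  list(features = mat, labels = df$label)
}
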