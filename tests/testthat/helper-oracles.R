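# Independent brute-force oracles. These deliberately avoid the package's
# indexed graph structures: they work from the raw triple table alone, so
# agreement with the implementation is a genuine cross-check.

# raw (subject, predicate, object, provenance-string) table of a graph
raw_triples <- function(graph) {
  tr <- graph$triples
  data.frame(subject = tr$subject, predicate = tr$predicate,
             object = tr$object,
             provenance = vapply(tr$provenance, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

# triple row indices joining a and b in either orientation, by full scan
bf_between <- function(tr, a, b) {
  which((tr$subject == a & tr$object == b) |
          (tr$subject == b & tr$object == a))
}

# brute-force path enumeration: triple-nested loops over the raw table
bf_paths <- function(combo, tr, proteins) {
  overlap <- lapply(sort(intersect(combo$drug_targets,
                                   combo$disease_proteins)),
                    function(p) list(dt = p, dp = p,
                                     triples = bf_between(tr, p, p)))
  direct <- list()
  indirect <- list()
  for (dt in sort(combo$drug_targets)) {
    for (dp in sort(combo$disease_proteins)) {
      if (dt == dp) next
      idx <- bf_between(tr, dt, dp)
      if (length(idx))
        direct[[length(direct) + 1L]] <- list(dt = dt, dp = dp, triples = idx)
      for (ip in proteins) {
        if (ip == dt || ip == dp) next
        a <- bf_between(tr, dt, ip)
        b <- bf_between(tr, ip, dp)
        if (length(a) && length(b))
          indirect[[length(indirect) + 1L]] <-
            list(dt = dt, ip = ip, dp = dp, dtip = a, ipdp = b)
      }
    }
  }
  list(overlap = overlap, direct = direct, indirect = indirect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared canonical record form so implementation output and brute-force
# output become directly comparable with expect_identical()
.canon1 <- function(r) {
  ip <- r$ip
  if (!is.null(ip) && is.na(ip)) ip <- NULL
  list(dt = r$dt, ip = ip %||% "", dp = r$dp,
       triples = sort(r$triples %||% integer()),
       dtip = sort(r$dtip %||% integer()),
       ipdp = sort(r$ipdp %||% integer()))
}

canon_records <- function(records) {
  out <- lapply(records, .canon1)
  keys <- vapply(out, function(r) paste(r$dt, r$ip, r$dp), "")
  out[order(keys)]
}

canon_bf <- canon_records

# feature-vector oracle: recompute slot/value sets from the brute-force paths
bf_features <- function(combo, graph, spec) {
  tr <- raw_triples(graph)
  paths <- bf_paths(combo, tr, graph$proteins)
  labels_of <- function(idx) {
    idx <- unique(idx)
    srcs <- unlist(strsplit(tr$provenance[idx], ";", fixed = TRUE))
    list(pred = unique(tr$predicate[idx]), src = unique(srcs))
  }
  self_idx <- unlist(lapply(paths$overlap, `[[`, "triples"))
  direct_idx <- unlist(lapply(paths$direct, `[[`, "triples"))
  dtip_idx <- unlist(lapply(paths$indirect, `[[`, "dtip"))
  ipdp_idx <- unlist(lapply(paths$indirect, `[[`, "ipdp"))
  sets <- list(SELF = labels_of(self_idx), DIRECT = labels_of(direct_idx),
               DTIP = labels_of(dtip_idx), IPDP = labels_of(ipdp_idx))
  bits <- integer(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    slot <- spec$slot[i]
    bits[i] <- switch(slot,
      OVERLAP_FLAG = as.integer(length(paths$overlap) > 0L),
      COOC_DIRECT = as.integer(length(paths$direct) > 0L),
      COOC_INDIRECT = as.integer(length(paths$indirect) > 0L),
      as.integer(spec$value[i] %in%
        (if (spec$kind[i] == "predicate") sets[[slot]]$pred
         else sets[[slot]]$src)))
  }
  names(bits) <- spec$id
  bits
}

# Floyd-Warshall all-pairs hop distances from the raw triple table
bf_distances <- function(graph) {
  prot <- graph$proteins
  n <- length(prot)
  D <- matrix(Inf, n, n, dimnames = list(prot, prot))
  diag(D) <- 0
  tr <- raw_triples(graph)
  for (i in seq_len(nrow(tr))) {
    a <- tr$subject[i]; b <- tr$object[i]
    if (a != b) D[a, b] <- D[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    through <- D[i, k] + D[k, ]
    upd <- through < D[i, ]
    D[i, upd] <- through[upd]
  }
  D
}

# small random multigraph, independent of the package's generator
random_test_graph <- function(n_proteins, n_triples, n_pred = 4L,
                              n_src = 3L, p_self = 0.05, seed = 1L) {
  set.seed(seed)
  prot <- sprintf("N%02d", seq_len(n_proteins))
  subj <- sample(prot, n_triples, replace = TRUE)
  obj <- sample(prot, n_triples, replace = TRUE)
  keep_self <- runif(n_triples) < p_self
  obj[obj == subj & !keep_self] <-
    sample(prot, sum(obj == subj & !keep_self), replace = TRUE)
  prov <- vapply(seq_len(n_triples), function(i)
    paste(sample(sprintf("S%d", seq_len(n_src)),
                 sample(1:2, 1L)), collapse = ";"), "")
  kg_graph(data.frame(
    subject = subj,
    predicate = sample(sprintf("p%d", seq_len(n_pred)), n_triples,
                       replace = TRUE),
    object = obj, provenance = prov, stringsAsFactors = FALSE),
    proteins = prot)
}

random_test_combo <- function(graph, dt_size = 3L, dp_size = 3L,
                              allow_overlap = TRUE, seed = 1L) {
  set.seed(seed)
  dt <- sample(graph$proteins, dt_size)
  dp <- if (allow_overlap) sample(graph$proteins, dp_size)
    else sample(setdiff(graph$proteins, dt), dp_size)
  combination(paste0("rc", seed), dt, dp, "unlabeled")
}
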