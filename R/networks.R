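#' Read a molecular interaction edge list
#'
#' Tab-separated columns `source`, `target`, `directness` (`direct` /
#' `indirect`), `relation` (`E` expression, `T` transcription, `P`
#' phosphorylation/dephosphorylation, `PP` protein-protein binding) and
#' optionally `sign` (`activating` / `inhibiting` / `unknown`). Vocabulary
#' violations are format errors naming the file line; duplicate (unordered
#' pair, relation) rows are deduplicated with a warning. Self-loops
#' (source == target) are kept as explicit self-regulation edges but are
#' never traversed during network growth.
#'
#' @param path TSV file path.
#' @return Class `interaction_graph`: a validated edge `data.frame`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_interactions(df, path)
}

relation_codes <- c("E", "T", "P", "PP")
directness_codes <- c("direct", "indirect")
sign_codes <- c("activating", "inhibiting", "unknown")

#' @rdname read_interactions
#' @param edges edge `data.frame` to validate.
#' @param path file name used in error messages (optional).
#' @export
validate_interactions <- function(edges, path = "<edges>") {
  need <- c("source", "target", "directness", "relation")
  missing <- setdiff(need, names(edges))
  if (length(missing) > 0) {
    stop("interaction table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"sign" %in% names(edges)) edges$sign <- "unknown"
  check_vocab <- function(col, vocab) {
    bad <- which(!edges[[col]] %in% vocab)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s '%s' at line %d of %s (expected one of: %s)",
                   col, edges[[col]][bad[1]], bad[1] + 1L, path,
                   paste(vocab, collapse = ", ")), call. = FALSE)
    }
  }
  check_vocab("directness", directness_codes)
  check_vocab("relation", relation_codes)
  check_vocab("sign", sign_codes)
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), edges$relation)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (pair, relation) edge(s) removed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges <- edges[, c("source", "target", "directness", "relation", "sign")]
  class(edges) <- c("interaction_graph", "data.frame")
  edges
}

#' @rdname read_interactions
#' @export
write_interactions <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

interaction_nodes <- function(edges) {
  sort(unique(c(edges$source, edges$target)))
}

#' Grow capped interaction networks around focus genes
#'
#' Greedy seeded growth: the seed is the unused focus gene with the most
#' distinct focus-gene neighbors (ties broken lexicographically); the
#' network then repeatedly absorbs the connected candidate with the most
#' edges into the current member set — focus genes preferred over
#' non-focus, remaining ties lexicographic — until `max_size` molecules or
#' no connected candidate remains. The network's focus genes are then
#' retired, so distinct networks are disjoint in their focus genes, and
#' growth repeats while unseeded focus genes remain in the graph. Each
#' network is scored with the hypergeometric upper tail of its focus-gene
#' overlap (see [score_network()]) and networks are ranked by score. The
#' procedure is fully deterministic.
#'
#' @param edges an `interaction_graph` (see [read_interactions()]).
#' @param focus character vector of focus (signature) gene ids.
#' @param max_size maximum molecules per network (default 35).
#' @param direct_only if `TRUE`, traverse only `direct` edges.
#' @return `data.frame` ranked by score: columns `rank`, `seed`,
#'   `n_molecules`, `focus_count`, `p_right`, `score`, `molecules`
#'   (comma-separated, sorted).
#' @export
build_networks <- function(edges, focus, max_size = 35, direct_only = FALSE) {
  stopifnot(inherits(edges, "data.frame"))
  if (max_size < 2) stop("max_size must be >= 2", call. = FALSE)
  focus <- unique(as.character(focus))
  universe <- interaction_nodes(edges)
  trav <- edges[edges$source != edges$target, , drop = FALSE]
  if (direct_only) trav <- trav[trav$directness == "direct", , drop = FALSE]
  focus_in <- intersect(focus, universe)
  if (length(focus_in) == 0) {
    warning("no focus gene appears in the interaction graph")
    return(data.frame(rank = integer(0), seed = character(0),
                      n_molecules = integer(0), focus_count = integer(0),
                      p_right = numeric(0), score = numeric(0),
                      molecules = character(0), stringsAsFactors = FALSE))
  }
  # multigraph adjacency: neighbor lists keep one entry per edge row
  nb <- split(c(trav$target, trav$source), c(trav$source, trav$target))
  neighbors_of <- function(v) {
    unlist(nb[intersect(v, names(nb))], use.names = FALSE)
  }
  unused <- sort(focus_in)
  used_focus <- character(0)
  nets <- list()
  while (length(unused) > 0) {
    seed_score <- vapply(unused, function(f) {
      length(intersect(unique(neighbors_of(f)), focus_in))
    }, integer(1))
    seed <- unused[seed_score == max(seed_score)][1]  # unused is sorted
    net <- seed
    while (length(net) < max_size) {
      cand <- setdiff(unique(neighbors_of(net)), c(net, used_focus))
      if (length(cand) == 0) break
      into <- vapply(cand, function(v) {
        sum(neighbors_of(v) %in% net)
      }, numeric(1))
      cand_focus <- cand %in% focus_in
      pool <- if (any(cand_focus)) cand[cand_focus] else cand
      pool_into <- into[match(pool, cand)]
      best <- pool[pool_into == max(pool_into)]
      net <- c(net, sort(best)[1])
    }
    net_focus <- intersect(net, focus_in)
    used_focus <- union(used_focus, net_focus)
    unused <- setdiff(unused, net_focus)
    sc <- score_network(net, focus, universe)
    nets[[length(nets) + 1]] <- data.frame(
      seed = seed, n_molecules = length(net),
      focus_count = length(net_focus),
      p_right = sc$p_right, score = sc$score,
      molecules = paste(sort(net), collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, nets)
  out <- out[order(-out$score, -out$focus_count, out$seed), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Hypergeometric score of a molecule set against the focus genes
#'
#' Delegates to the same hypergeometric kernel as [fisher_enrichment()]:
#' `p_right = P(X >= k)` with `N = |universe|`, `K = |focus in universe|`,
#' `n = |net|`, `k = |net in focus|`; `score = -log10(p_right)`.
#'
#' @param net character vector of network molecules, a subset of `universe`.
#' @param focus focus gene ids.
#' @param universe all nodes of the interaction graph.
#' @return List with `p_right`, `score`, and the table margins
#'   `k`, `K`, `n`, `N`.
#' @export
score_network <- function(net, focus, universe) {
  net <- unique(as.character(net))
  universe <- unique(as.character(universe))
  stray <- setdiff(net, universe)
  if (length(stray) > 0) {
    stop("network molecule(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  K <- length(intersect(focus, universe))
  k <- length(intersect(net, focus))
  p <- hyper_p_right(k, K, length(net), length(universe))
  list(p_right = p, score = -log10(p), k = k, K = K,
       n = length(net), N = length(universe))
}

#' Sign-consistency activity call for a regulator
#'
#' An open analog of upstream-regulator activation prediction: over the
#' regulator's signed outgoing edges whose targets carry an up/down
#' fold-change direction, each target scores +1 when concordant (activating
#' edge and target up, or inhibiting edge and target down) and -1
#' otherwise. `z = sum / sqrt(n_targets)`; the call is `activated` when
#' `z >= 2`, `inhibited` when `z <= -2`, otherwise `indeterminate` (the
#' usual |z| >= 2 convention).
#'
#' @param edges an `interaction_graph`.
#' @param fc fold-change table from [compute_logfc()].
#' @param regulator node id with at least one signed edge to a gene in `fc`.
#' @return List with `z`, `call`, and `n_targets`.
#' @export
regulator_activity <- function(edges, fc, regulator) {
  out_edges <- edges[edges$source == regulator &
                       edges$sign %in% c("activating", "inhibiting"), ,
                     drop = FALSE]
  dir_map <- stats::setNames(fc$direction, fc$gene_id)
  out_edges <- out_edges[out_edges$target %in% names(dir_map), , drop = FALSE]
  tgt_dir <- dir_map[out_edges$target]
  keep <- tgt_dir %in% c("up", "down")
  out_edges <- out_edges[keep, , drop = FALSE]
  tgt_dir <- tgt_dir[keep]
  if (nrow(out_edges) == 0) {
    stop("regulator '", regulator,
         "' has no signed target with a fold-change direction", call. = FALSE)
  }
  concordant <- (out_edges$sign == "activating" & tgt_dir == "up") |
    (out_edges$sign == "inhibiting" & tgt_dir == "down")
  ct <- ifelse(concordant, 1, -1)
  z <- sum(ct) / sqrt(length(ct))
  call <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else
    "indeterminate"
  list(z = z, call = call, n_targets = length(ct))
}
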