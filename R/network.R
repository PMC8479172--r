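# Residue correlation networks and allosteric-path analysis. Nodes are
# residues (protein, ligand residues, ions); an edge joins i and j when
# |C_ij| meets the threshold (default 0.7, an angle between motion vectors
# of < 45 deg), weighted w_ij = -ln|C_ij| so that strong correlation means
# short graph distance. Communities come from greedy modularity
# agglomeration; suboptimal paths are the k lowest-weight simple paths.

#' Build a residue network from a cross-correlation matrix
#'
#' @param corr A `ccmatrix` (or bare symmetric matrix with unit diagonal).
#' @param threshold Correlation threshold in (0, 1); edge iff
#'   `|C_ij| >= threshold` (default 0.7).
#' @return A `residue_network`: list with `graph` (igraph, undirected,
#'   edge attributes `weight = -ln|C|` and `corr = C_ij`), `threshold`,
#'   `nodes` (residue labels).
#' @export
build_network <- function(corr, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  C <- if (inherits(corr, "ccmatrix")) corr$C else corr
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  if (any(abs(diag(C) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal")
  }
  nodes <- if (!is.null(rownames(C))) rownames(C) else
    as.character(seq_len(nrow(C)))
  nodes <- make.unique(nodes)
  adj <- abs(C) >= threshold
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(C), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.numeric(t(idx)))
    cij <- C[idx]
    igraph::E(g)$corr <- cij
    igraph::E(g)$weight <- -log(abs(cij))
  }
  structure(list(graph = g, threshold = threshold, nodes = nodes),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("residue network: %d nodes, %d edges (|C| >= %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold))
  invisible(x)
}

#' Detect communities by greedy modularity maximisation
#'
#' Agglomerative greedy modularity (fast-greedy), using |C_ij| as the edge
#' strength. An edgeless network places every node in its own community,
#' with a warning.
#'
#' @param net A `residue_network`.
#' @return A `community_partition`: list with `membership` (named integer),
#'   `modularity`, `sizes`.
#' @export
detect_communities <- function(net) {
  g <- net$graph
  if (!igraph::ecount(g)) {
    warning("edgeless network: every node is its own community")
    memb <- setNames(seq_len(igraph::vcount(g)), net$nodes)
    return(structure(list(membership = memb, modularity = NA_real_,
                          sizes = table(memb)),
                     class = "community_partition"))
  }
  cm <- igraph::cluster_fast_greedy(g, weights = abs(igraph::E(g)$corr))
  # cut the merge tree at the modularity maximum; numerical ties resolve
  # to the smaller community count
  best_step <- max(which(cm$modularity >= max(cm$modularity) - 1e-12))
  k_best <- igraph::vcount(g) - (best_step - 1L)
  memb <- setNames(as.integer(igraph::cut_at(cm, no = k_best)), net$nodes)
  structure(list(membership = memb,
                 modularity = max(cm$modularity),
                 sizes = table(memb)),
            class = "community_partition")
}

#' Community-level summary graph
#'
#' Collapses the residue network into one node per community with radius
#' `R_i = N_i / 3` (N_i the community size). The edge weight between two
#' connected communities is `E_ij = -ln|max(C_ij)| / 4` for the
#' structure-overlay variant and `E_ij = -ln|max(C_ij)|` for the
#' simplified variant, where max(C_ij) is the strongest correlation among
#' residue pairs spanning the two communities that carry network edges.
#' Communities with no inter-community edges are pruned.
#'
#' @param partition A `community_partition`.
#' @param net The underlying `residue_network`.
#' @param variant `"overlay"` or `"simplified"`.
#' @param coords Optional n x 3 residue coordinates for geometric centres
#'   (overlay variant).
#' @return A `community_graph`: list with `nodes` (data.frame id, size,
#'   radius, optional centre), `edges` (data.frame i, j, max_corr, weight),
#'   `variant`.
#' @export
community_graph <- function(partition, net,
                            variant = c("overlay", "simplified"),
                            coords = NULL) {
  variant <- match.arg(variant)
  memb <- partition$membership
  g <- net$graph
  el <- igraph::as_edgelist(g, names = TRUE)
  ec <- if (igraph::ecount(g)) igraph::E(g)$corr else numeric(0)
  ci <- memb[el[, 1]]; cj <- memb[el[, 2]]
  cross <- ci != cj
  edges <- NULL
  if (any(cross)) {
    key <- paste(pmin(ci[cross], cj[cross]), pmax(ci[cross], cj[cross]))
    mx <- tapply(abs(ec[cross]), key, max)
    ij <- do.call(rbind, strsplit(names(mx), " "))
    w <- -log(mx)
    if (variant == "overlay") w <- w / 4
    edges <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                        max_corr = as.numeric(mx), weight = as.numeric(w))
  }
  connected <- if (is.null(edges)) integer(0) else unique(c(edges$i, edges$j))
  sizes <- table(memb)
  ids <- as.integer(names(sizes))
  keep <- ids %in% connected
  nodes <- data.frame(id = ids[keep],
                      size = as.integer(sizes[keep]),
                      radius = as.integer(sizes[keep]) / 3)
  if (!is.null(coords)) {
    ctr <- t(vapply(nodes$id, function(k) {
      colMeans(coords[memb == k, , drop = FALSE])
    }, numeric(3)))
    nodes$cx <- ctr[, 1]; nodes$cy <- ctr[, 2]; nodes$cz <- ctr[, 3]
  }
  structure(list(nodes = nodes, edges = edges, variant = variant),
            class = "community_graph")
}

#' Node centralities of the residue network
#'
#' Degree (incident edge count) and betweenness (shortest paths through
#' the node, endpoints excluded) on the full residue network. Weighted
#' (`-ln|C|`) shortest paths by default; `weighted = FALSE` switches to
#' hop counts.
#'
#' @param net A `residue_network`.
#' @param weighted Use the `-ln|C|` edge weights (default TRUE).
#' @return data.frame (node, degree, betweenness).
#' @export
network_centrality <- function(net, weighted = TRUE) {
  g <- net$graph
  w <- if (weighted && igraph::ecount(g)) igraph::E(g)$weight else NA
  btw <- igraph::betweenness(g, directed = FALSE,
                             weights = if (identical(w, NA)) NULL else w)
  data.frame(node = net$nodes,
             degree = as.integer(igraph::degree(g)),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE)
}

#' Suboptimal paths between residue sets
#'
#' The k lowest-weight simple paths between any source and any sink node,
#' merged across all source-sink pairs and globally sorted by total weight
#' (ties broken lexicographically by node sequence). Disconnected pairs
#' contribute nothing; if all pairs are disconnected an empty path set is
#' returned with a warning.
#'
#' @param net A `residue_network`.
#' @param sources,sinks Node names (character) or indices.
#' @param k Number of paths retained after the merge (default 500).
#' @return A `path_set`: list with `paths` (list of node-name vectors),
#'   `weights` (non-decreasing), `sources`, `sinks`.
#' @export
suboptimal_paths <- function(net, sources, sinks, k = 500) {
  g <- net$graph
  sources <- .as_node_names(net, sources)
  sinks <- .as_node_names(net, sinks)
  all_paths <- list(); all_w <- numeric(0)
  for (s in sources) {
    for (t in setdiff(sinks, s)) {
      comp <- igraph::components(g)$membership
      if (comp[s] != comp[t]) next
      ksp <- igraph::k_shortest_paths(g, from = s, to = t, k = k,
                                      weights = igraph::E(g)$weight)
      for (p in ksp$vpaths) {
        nodes <- igraph::as_ids(p)
        all_paths[[length(all_paths) + 1L]] <- nodes
        all_w <- c(all_w, .path_weight(g, nodes))
      }
    }
  }
  if (!length(all_paths)) {
    warning("no source-sink pair is connected; empty path set")
    return(structure(list(paths = list(), weights = numeric(0),
                          sources = sources, sinks = sinks),
                     class = "path_set"))
  }
  keys <- vapply(all_paths, paste, character(1), collapse = ">")
  dup <- duplicated(keys)
  all_paths <- all_paths[!dup]; all_w <- all_w[!dup]; keys <- keys[!dup]
  ord <- order(all_w, keys)
  keep <- head(ord, k)
  structure(list(paths = all_paths[keep], weights = all_w[keep],
                 sources = sources, sinks = sinks),
            class = "path_set")
}

.as_node_names <- function(net, x) {
  x <- as.character(x)
  missing <- setdiff(x, net$nodes)
  if (length(missing)) {
    stop("unknown network node(s): ", paste(missing, collapse = ", "))
  }
  x
}

.path_weight <- function(g, nodes) {
  if (length(nodes) < 2) return(0)
  eids <- igraph::get_edge_ids(g, rbind(nodes[-length(nodes)], nodes[-1]))
  sum(igraph::E(g)$weight[eids])
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("path set: %d paths, weights %.4g .. %.4g\n",
              length(x$paths),
              if (length(x$weights)) min(x$weights) else NA,
              if (length(x$weights)) max(x$weights) else NA))
  invisible(x)
}

#' Fraction of paths passing through a node set
#'
#' Endpoints are excluded: a path counts only if an interior node belongs
#' to the set.
#'
#' @param paths A `path_set`.
#' @param nodes Node names (character) or indices.
#' @return Fraction in [0, 1].
#' @export
fraction_through <- function(paths, nodes) {
  if (!length(paths$paths)) stop("empty path set")
  nodes <- as.character(nodes)
  hits <- vapply(paths$paths, function(p) {
    interior <- if (length(p) > 2) p[-c(1, length(p))] else character(0)
    any(interior %in% nodes)
  }, logical(1))
  mean(hits)
}

#' Similarity between two community partitions
#'
#' For each community of the first partition, the best Jaccard overlap
#' (as a percentage) with any community of the second; pairs at or above
#' `analogy_threshold` are labelled analogous.
#'
#' @param pA,pB `community_partition` objects over the same node universe.
#' @param analogy_threshold Percentage above which communities count as
#'   analogous (default 60).
#' @return data.frame (community, size, best_match, overlap_pct,
#'   analogous) with attribute `n_analogous`.
#' @export
partition_similarity <- function(pA, pB, analogy_threshold = 60) {
  if (!setequal(names(pA$membership), names(pB$membership))) {
    stop("partitions cover different node universes")
  }
  mb <- pB$membership[names(pA$membership)]
  ids_a <- sort(unique(pA$membership))
  out <- do.call(rbind, lapply(ids_a, function(a) {
    set_a <- names(pA$membership)[pA$membership == a]
    ov <- vapply(sort(unique(mb)), function(b) {
      set_b <- names(mb)[mb == b]
      length(intersect(set_a, set_b)) / length(union(set_a, set_b))
    }, numeric(1))
    best <- which.max(ov)
    data.frame(community = a, size = length(set_a),
               best_match = sort(unique(mb))[best],
               overlap_pct = 100 * ov[best])
  }))
  out$analogous <- out$overlap_pct >= analogy_threshold
  attr(out, "n_analogous") <- sum(out$analogous)
  out
}

#' Export a residue network as an edge-list TSV
#' @param net A `residue_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_tsv <- function(net, path) {
  g <- net$graph
  el <- igraph::as_edgelist(g)
  df <- data.frame(node_i = el[, 1], node_j = el[, 2],
                   corr = if (igraph::ecount(g)) igraph::E(g)$corr else numeric(0),
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a residue network as GraphML
#' @param net A `residue_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' Export a path set as TSV (one node sequence + weight per row)
#' @param paths A `path_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paths_tsv <- function(paths, path) {
  df <- data.frame(
    rank = seq_along(paths$paths),
    weight = paths$weights,
    nodes = vapply(paths$paths, paste, character(1), collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
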