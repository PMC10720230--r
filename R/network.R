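#' Build a multimorbidity network from selected patterns
#'
#' Nodes are the union of endpoints of the selected patterns, with chapter,
#' prevalence and count attributes taken from the disease table; edges carry
#' the pattern's odds ratio, p-value and frequency. Nodes are stored in
#' lexicographic order so all downstream outputs are deterministic.
#'
#' @param selected pattern table in which every row has `selected = TRUE`
#'   (pass `subset(screenPatterns(x), selected)`); a row not flagged
#'   selected is a contract violation and raises an error.
#' @param prevalence optional disease table from [diseasePrevalence()] used
#'   to attach node attributes.
#' @param label network name.
#' @return a [MultimorbidityNetwork-class].
#' @export
buildNetwork <- function(selected, prevalence = NULL, label = "network") {
  if (nrow(selected) > 0) {
    if (is.null(selected$selected) || !all(selected$selected))
      stop("buildNetwork() requires patterns flagged selected = TRUE")
  }
  nodes <- sort(unique(c(as.character(selected$code_i),
                         as.character(selected$code_j))))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(nodes)) {
    igraph::V(g)$name <- nodes
    if (!is.null(prevalence)) {
      m <- match(nodes, prevalence$code)
      igraph::V(g)$chapter <- prevalence$chapter[m]
      igraph::V(g)$prevalence <- prevalence$prevalence[m]
      igraph::V(g)$count <- prevalence$count[m]
    } else {
      igraph::V(g)$chapter <- icdChapter(nodes)
      igraph::V(g)$prevalence <- NA_real_
      igraph::V(g)$count <- NA_real_
    }
  }
  if (nrow(selected)) {
    g <- igraph::add_edges(
      g, rbind(match(selected$code_i, nodes), match(selected$code_j, nodes)),
      odds_ratio = selected$odds_ratio,
      p_value = selected$p_value,
      frequency = selected$frequency)
  }
  new("MultimorbidityNetwork", graph = g, label = label)
}

#' Enumerate all maximal cliques of a network
#'
#' Complete enumeration via igraph's pivoting Bron-Kerbosch implementation.
#' Isolated nodes yield singleton maximal cliques.
#'
#' @param network a [MultimorbidityNetwork-class].
#' @return list of character vectors (node codes, sorted within a clique),
#'   ordered by decreasing size then lexicographically.
#' @export
enumerateMaximalCliques <- function(network) {
  g <- networkGraph(network)
  cl <- igraph::max_cliques(g, min = 1L)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  first <- vapply(cl, `[`, character(1), 1L)
  cl[order(-lengths(cl), first)]
}

#' Maximal clique centrality (MCC)
#'
#' For node `v`, `MCC(v)` is the sum over the maximal cliques `C` of size at
#' least 2 that contain `v` of `(|C| - 1)!`. When `v`'s neighborhood
#' contains no internal edges every such clique is a single edge and MCC
#' reduces to the degree; an isolated node has MCC 0.
#'
#' @param network a [MultimorbidityNetwork-class].
#' @param nodes character vector of node codes (default: all nodes).
#' @return named numeric vector of MCC values (exact integers; clique sizes
#'   in disease networks are far below the 18-node exactness limit of
#'   double-precision factorials).
#' @export
mcc <- function(network, nodes = NULL) {
  g <- networkGraph(network)
  all_nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- all_nodes
  if (!all(nodes %in% all_nodes))
    stop("node(s) not in network: ",
         paste(setdiff(nodes, all_nodes), collapse = ", "))
  out <- setNames(numeric(length(all_nodes)), all_nodes)
  cl <- igraph::max_cliques(g, min = 2L)
  for (C in cl) {
    members <- igraph::V(g)$name[C]
    out[members] <- out[members] + factorial(length(C) - 1L)
  }
  out[nodes]
}

#' Compute the seven node metrics of a multimorbidity network
#'
#' Degree; maximal clique centrality ([mcc()]); closeness with the
#' Wasserman-Faust scaling for disconnected graphs (per-component closeness
#' times `(component size - 1)/(n - 1)`, 0 for isolated nodes); local
#' clustering coefficient (0 when degree < 2); betweenness on the full
#' unweighted graph (vertex pairs in different components contribute
#' nothing); PageRank with damping 0.85 and uniform personalization;
#' eigencentrality as the principal adjacency eigenvector of the largest
#' connected component (ties broken towards the component holding the
#' lexicographically smallest code), 0 elsewhere, max-normalized. All
#' metrics treat the graph as unweighted and undirected: edge odds ratios
#' and frequencies are annotations, not weights.
#'
#' @param network a [MultimorbidityNetwork-class].
#' @return data.frame with one row per node (sorted by code): `code`,
#'   `degree`, `mcc`, `closeness`, `clustering_coefficient`, `betweenness`,
#'   `pagerank`, `eigencentrality`.
#' @export
computeMetrics <- function(network) {
  g <- networkGraph(network)
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(code = character(0), degree = integer(0),
                      mcc = numeric(0), closeness = numeric(0),
                      clustering_coefficient = numeric(0),
                      betweenness = numeric(0), pagerank = numeric(0),
                      eigencentrality = numeric(0)))
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)

  # closeness, Wasserman-Faust: (nc-1)/sum(d) * (nc-1)/(n-1) per component
  comp <- igraph::components(g)
  D <- igraph::distances(g)
  clo <- numeric(n)
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    nc <- length(idx)
    if (nc < 2L || n < 2L) { clo[idx] <- 0; next }
    dsum <- rowSums(D[idx, idx, drop = FALSE])
    clo[idx] <- (nc - 1) / dsum * (nc - 1) / (n - 1)
  }

  clu <- igraph::transitivity(g, type = "local", isolates = "zero",
                              vids = igraph::V(g))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  pr <- igraph::page_rank(g, damping = 0.85)$vector

  eig <- numeric(n)
  if (igraph::ecount(g) > 0) {
    sizes <- comp$csize
    big <- which(sizes == max(sizes))
    if (length(big) > 1L) {
      # tie: component containing the smallest code among the largest ones
      firsts <- vapply(big, function(k)
        min(nodes[comp$membership == k]), character(1))
      big <- big[order(firsts)[1L]]
    }
    idx <- which(comp$membership == big)
    sub <- igraph::induced_subgraph(g, idx)
    ev <- igraph::eigen_centrality(sub)$vector
    eig[idx] <- ev[match(nodes[idx], igraph::V(sub)$name)]
    if (max(eig) > 0) eig <- eig / max(eig)
  }

  out <- data.frame(code = nodes, degree = as.integer(deg), mcc = mcc(network),
                    closeness = clo, clustering_coefficient = clu,
                    betweenness = btw, pagerank = unname(pr),
                    eigencentrality = eig, stringsAsFactors = FALSE)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subnetwork associated with a set of hub diseases
#'
#' Keeps every edge with at least one endpoint among the hubs; the node set
#' is the endpoints of those edges plus any edgeless hub. Attributes are
#' preserved.
#'
#' @param network a [MultimorbidityNetwork-class].
#' @param hubs character vector of hub node codes (must exist in the
#'   network).
#' @return a [MultimorbidityNetwork-class] labelled
#'   `"<label>_hub_associated"`.
#' @export
hubAssociatedSubnetwork <- function(network, hubs) {
  g <- networkGraph(network)
  nodes <- igraph::V(g)$name
  if (!all(hubs %in% nodes))
    stop("hub(s) not in network: ",
         paste(setdiff(hubs, nodes), collapse = ", "))
  eids <- unique(unlist(lapply(
    igraph::incident_edges(g, hubs), as.integer)))
  ends <- igraph::ends(g, eids, names = TRUE)
  keep_nodes <- sort(unique(c(as.vector(ends), hubs)))
  sg <- igraph::induced_subgraph(g, keep_nodes)
  inc <- unique(unlist(lapply(
    igraph::incident_edges(sg, hubs), as.integer)))
  sg <- igraph::delete_edges(sg, setdiff(seq_len(igraph::ecount(sg)), inc))
  new("MultimorbidityNetwork", graph = sg,
      label = paste0(objectLabel(network), "_hub_associated"))
}

#' Export a network as GraphML plus node/edge CSV tables
#'
#' Node attributes: chapter, prevalence, count and the seven metrics; edge
#' attributes: odds ratio, p-value, frequency.
#'
#' @param network a [MultimorbidityNetwork-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default: the network label).
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(network, dir, prefix = objectLabel(network)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  metrics <- computeMetrics(network)
  g <- networkGraph(network)
  if (igraph::vcount(g) > 0) {
    m <- match(igraph::V(g)$name, metrics$code)
    for (col in setdiff(names(metrics), "code"))
      g <- igraph::set_vertex_attr(g, col, value = metrics[[col]][m])
  }
  paths <- c(
    graphml = file.path(dir, paste0(prefix, ".graphml")),
    nodes = file.path(dir, paste0(prefix, "_nodes.csv")),
    edges = file.path(dir, paste0(prefix, "_edges.csv"))
  )
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  data.table::fwrite(merge(nodeTable(network), metrics, by = "code"),
                     paths[["nodes"]])
  data.table::fwrite(edgeTable(network), paths[["edges"]])
  invisible(paths)
}
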