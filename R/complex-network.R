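## Networks of protein complexes carrying mutations in multiple
## subunits.

#' Build the mutated-complex interaction network
#'
#' Two mutated genes are connected when they map to different subunits
#' (chains) of at least one template structure with sequence identity
#' strictly above the threshold on both chains; a gene mapping to two or
#' more chains of one structure gets a self-loop (homooligomer). Genes
#' without a mapped variant are excluded. Edge attribute `structures`
#' lists the supporting structure ids.
#'
#' @param hits template hit table (gene_id, structure_id, chain, seq_id);
#'   typically the union of [search_templates()] results.
#' @param mutated_genes character vector of genes carrying at least one
#'   mapped variant.
#' @param identity_threshold minimum identity, strict (default 0.90).
#' @return an igraph graph (undirected, self-loops allowed).
#' @export
build_network <- function(hits, mutated_genes, identity_threshold = 0.90) {
  h <- hits[hits$seq_id > identity_threshold &
              hits$gene_id %in% mutated_genes, , drop = FALSE]
  edges <- list()
  for (sid in unique(h$structure_id)) {
    hs <- h[h$structure_id == sid, , drop = FALSE]
    ## one mapping per (gene, chain)
    hs <- hs[!duplicated(paste(hs$gene_id, hs$chain)), , drop = FALSE]
    if (nrow(hs) < 2) next
    for (i in seq_len(nrow(hs) - 1)) for (j in (i + 1):nrow(hs)) {
      if (hs$chain[i] == hs$chain[j]) next
      a <- hs$gene_id[i]; b <- hs$gene_id[j]
      key <- paste(sort(c(a, b)), collapse = "|")
      edges[[key]] <- unique(c(edges[[key]], sid))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(unique(h$gene_id))
  if (length(edges)) {
    pairs <- do.call(rbind, strsplit(names(edges), "|", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(pairs)))
    igraph::E(g)$structures <- vapply(edges, paste, "", collapse = ",")
  }
  g
}

#' Complexes with mutations in multiple subunits
#'
#' Connected components of the mutated-complex network that have at
#' least two members or a self-loop (homooligomers of one mutated gene);
#' isolated loop-free genes correspond to complexes with a single
#' mutated subunit and are dropped.
#'
#' @param graph a [build_network()] result.
#' @return list of character vectors (component members), sorted by
#'   decreasing size then lexicographically.
#' @export
multi_mutated_complexes <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list())
  comp <- igraph::components(graph)
  loops <- igraph::which_loop(graph)
  loop_vertices <- unique(igraph::ends(graph, igraph::E(graph))[loops, 1])
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == ci])
    if (length(members) >= 2 || any(members %in% loop_vertices))
      out[[length(out) + 1L]] <- members
  }
  sizes <- vapply(out, length, 0L)
  first <- vapply(out, function(m) m[1], "")
  out[order(-sizes, first)]
}

#' Export a network as an edge-list TSV
#' @param graph igraph graph from [build_network()].
#' @param path output file.
#' @export
write_network <- function(graph, path) {
  if (igraph::ecount(graph)) {
    e <- igraph::ends(graph, igraph::E(graph))
    df <- data.frame(gene_a = e[, 1], gene_b = e[, 2],
                     structures = igraph::E(graph)$structures)
  } else {
    df <- data.frame(gene_a = character(), gene_b = character(),
                     structures = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
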