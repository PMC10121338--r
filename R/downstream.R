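#' Global view of a result set
#'
#' Union graph of all result patterns: nodes are the genes taking part in at
#' least one pattern, an edge joins two genes connected in at least one
#' pattern, and the edge weight counts the patterns containing that edge.
#' Connected components are labelled, and components of size 4 or less are
#' flagged as below the usual enrichment-analysis threshold (they are kept,
#' not dropped).
#'
#' @param results A `wgm_patterns` tibble (see [top_k_patterns()]).
#' @return A `wgm_global_view` object: list with `edges`
#'   (tibble `gene_a`, `gene_b`, `weight`), `nodes` (tibble `gene`,
#'   `component`, `component_size`, `small_component`) and the igraph
#'   object in `graph`.
#' @export
build_global_view <- function(results) {
  all_edges <- unlist(results$edges)
  if (!length(all_edges)) {
    return(structure(list(edges = tibble(gene_a = character(),
                                         gene_b = character(),
                                         weight = integer()),
                          nodes = tibble(gene = character(),
                                         component = integer(),
                                         component_size = integer(),
                                         small_component = logical()),
                          graph = igraph::make_empty_graph(directed = FALSE)),
                     class = "wgm_global_view"))
  }
  tab <- sort(table(all_edges))
  ends <- split_edges(names(tab))
  edges <- tibble(gene_a = ends[, 1], gene_b = ends[, 2],
                  weight = as.integer(tab)) %>%
    arrange(.data$gene_a, .data$gene_b)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- edges$weight
  comp <- igraph::components(g)
  nodes <- tibble(gene = names(comp$membership),
                  component = as.integer(comp$membership),
                  component_size = as.integer(comp$csize[comp$membership])) %>%
    mutate(small_component = .data$component_size <= 4) %>%
    arrange(.data$gene)
  structure(list(edges = edges, nodes = nodes, graph = g),
            class = "wgm_global_view")
}

#' @export
print.wgm_global_view <- function(x, ...) {
  cat("<wgm_global_view> ", nrow(x$nodes), " genes, ", nrow(x$edges),
      " edges, ", length(unique(x$nodes$component)), " component(s)\n",
      sep = "")
  invisible(x)
}

#' Write a global view to disk
#'
#' Writes the union graph both as GraphML and as a weighted edge-list TSV.
#'
#' @param gv A `wgm_global_view`.
#' @param prefix Output path prefix (`<prefix>.graphml`, `<prefix>.tsv`).
#' @return Invisibly, the file paths.
#' @export
write_global_view <- function(gv, prefix) {
  stopifnot(inherits(gv, "wgm_global_view"))
  gml <- paste0(prefix, ".graphml")
  tsv <- paste0(prefix, ".tsv")
  igraph::write_graph(gv$graph, gml, format = "graphml")
  readr::write_tsv(gv$edges, tsv)
  invisible(c(graphml = gml, tsv = tsv))
}

#' Gene co-occurrence frequencies in a result set
#'
#' Counts, over the result patterns, how often each gene (or pair, triple,
#' quadruple of genes) co-occurs inside the same pattern: every size-`arity`
#' subset of a pattern's node set contributes one count for that pattern.
#'
#' @param results A `wgm_patterns` tibble.
#' @param arity Tuple size, 1 to 4.
#' @return A tibble with columns `gene_1`, ..., `gene_<arity>`, `count`,
#'   ranked by decreasing count (ties by tuple key).
#' @export
cooccurrence_frequencies <- function(results, arity = 1) {
  if (!arity %in% 1:4) abort("arity must be 1, 2, 3 or 4")
  tuples <- unlist(lapply(results$nodes, function(nd) {
    nd <- sort(unique(nd))
    if (length(nd) < arity) return(character())
    apply(combn(nd, arity), 2, paste, collapse = ";")
  }))
  gcols <- paste0("gene_", seq_len(arity))
  if (!length(tuples)) {
    out <- as_tibble(stats::setNames(
      c(rep(list(character()), arity), list(integer())), c(gcols, "count")))
    return(out)
  }
  tab <- table(tuples)
  parts <- do.call(rbind, strsplit(names(tab), ";", fixed = TRUE))
  out <- as_tibble(stats::setNames(as.data.frame(parts,
                                                 stringsAsFactors = FALSE),
                                   gcols))
  out$count <- as.integer(tab)
  out[order(-out$count, names(tab)), ]
}

#' Flag hub proteins in a PPI network
#'
#' Computes the degree of each gene of interest on the full protein-protein
#' interaction graph (self-loops and duplicate undirected edges dropped) and
#' flags hubs: nodes of degree at least `threshold` (10 by convention).
#' Genes absent from the PPI graph are reported with degree 0.
#'
#' @param ppi Two-column data frame (or tibble) of interacting identifiers,
#'   as exportable from interaction databases.
#' @param genes Character vector of genes of interest (e.g.
#'   `build_global_view(results)$nodes$gene`).
#' @param threshold Minimum degree for the hub flag (at least 1).
#' @return A tibble `gene`, `degree`, `hub`, in decreasing degree order.
#' @export
flag_hubs <- function(ppi, genes, threshold = 10) {
  if (threshold < 1) abort("threshold must be at least 1")
  ppi <- as.data.frame(ppi)[, 1:2]
  names(ppi) <- c("a", "b")
  ppi$a <- as.character(ppi$a); ppi$b <- as.character(ppi$b)
  ppi <- ppi[ppi$a != ppi$b, ]
  key <- edge_key(ppi$a, ppi$b)
  ppi <- ppi[!duplicated(key), ]
  deg <- table(c(ppi$a, ppi$b))
  d <- as.integer(deg[genes])
  d[is.na(d)] <- 0L
  tibble(gene = genes, degree = d, hub = d >= threshold) %>%
    arrange(desc(.data$degree), .data$gene)
}

#' Write a pattern result set to disk
#'
#' Writes one record per pattern as pretty-printed JSON
#' (`<prefix>.json`) and as a flat TSV (`<prefix>.tsv`, edge list
#' semicolon-joined).
#'
#' @param results A `wgm_patterns` tibble.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_patterns <- function(results, prefix) {
  flat <- as_tibble(results) %>%
    mutate(edges = vapply(.data$edges, paste, "", collapse = ";"),
           nodes = vapply(.data$nodes, paste, "", collapse = ";"))
  jf <- paste0(prefix, ".json")
  tf <- paste0(prefix, ".tsv")
  meta <- list(guiding_class = attr(results, "guiding_class"),
               other_class = attr(results, "other_class"),
               x = attr(results, "x"),
               log_base = attr(results, "log_base"),
               n_guiding = attr(results, "n_guiding"),
               n_other = attr(results, "n_other"))
  jsonlite::write_json(list(meta = meta, patterns = flat), jf,
                       pretty = TRUE, auto_unbox = TRUE, digits = 12)
  readr::write_tsv(flat, tf)
  invisible(c(json = jf, tsv = tf))
}
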