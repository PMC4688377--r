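#' Construct an undirected protein-protein interaction network
#'
#' Builds a simple undirected graph over gene symbols from a two-column edge
#' table. Symbols are whitespace-trimmed and uppercased, self-loops are
#' dropped, and duplicate (unordered) edges are collapsed, so the resulting
#' graph satisfies the assumptions of the neighborhood-enrichment statistic.
#'
#' @param edges two-column character matrix or data frame of gene symbol
#'   pairs; extra columns are ignored.
#' @param nodes optional character vector of additional node symbols (e.g.
#'   isolated proteins with no recorded interaction).
#' @param quiet suppress the message reporting dropped self-loops/duplicates.
#'
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (character vector), `edges` (two-column character matrix, each row an
#'   unordered pair with the lexicographically smaller symbol first) and
#'   `adjacency` (named list mapping each node to its neighbor set).
#' @export
ppi_network <- function(edges, nodes = NULL, quiet = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L)
    stop("edge table must have at least two columns of gene symbols")
  a <- toupper(trimws(as.character(edges[, 1L])))
  b <- toupper(trimws(as.character(edges[, 2L])))
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  n_self <- sum(a == b)
  ok <- a != b
  a <- a[ok]; b <- b[ok]
  # canonical unordered orientation, then dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  all_nodes <- sort(unique(c(lo, hi,
                             if (!is.null(nodes)) toupper(trimws(nodes)))))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  adj <- vector("list", length(all_nodes))
  names(adj) <- all_nodes
  for (g in all_nodes) adj[[g]] <- character(0)
  if (length(lo)) {
    nb <- split(c(hi, lo), c(lo, hi))
    for (g in names(nb)) adj[[g]] <- sort(unique(nb[[g]]))
  }
  if (!quiet && (n_self > 0L || n_dup > 0L))
    message(sprintf("ppi_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  structure(list(nodes = all_nodes,
                 edges = cbind(from = lo, to = hi),
                 adjacency = adj),
            class = "ppi_network")
}

#' Load a PPI network from an edge-list file
#'
#' Reads a tab- or whitespace-delimited edge list of gene symbols (HPRD
#' flat-file style: first two columns are the interacting symbols, any
#' further columns are ignored). An optional one-column node-list file adds
#' isolated nodes.
#'
#' @param path path to the edge-list file.
#' @param node_path optional path to a one-symbol-per-line node list.
#' @param quiet suppress ingest messages.
#' @return A [ppi_network] object.
#' @export
load_network <- function(path, node_path = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read network file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no valid edges in network file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop(sprintf("malformed edge at line %d of %s: fewer than two columns",
                 bad[1L], path))
  edges <- cbind(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  nodes <- NULL
  if (!is.null(node_path)) {
    if (!file.exists(node_path)) stop("cannot read node file: ", node_path)
    nodes <- trimws(readLines(node_path, warn = FALSE))
    nodes <- nodes[nzchar(nodes) & !startsWith(nodes, "#")]
  }
  net <- ppi_network(edges, nodes = nodes, quiet = quiet)
  if (!quiet)
    message(sprintf("load_network: %d nodes, %d edges from %s",
                    length(net$nodes), nrow(net$edges), path))
  net
}

#' Write a network back to a two-column edge list
#'
#' @param net a [ppi_network].
#' @param path output file path.
#' @param node_path optional path for a one-column node list (written so that
#'   isolated nodes survive a round trip).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, node_path = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(node_path))
    writeLines(net$nodes, node_path)
  invisible(path)
}

#' Immediate neighbors of a gene
#'
#' @param net a [ppi_network].
#' @param gene gene symbol (case-insensitive).
#' @return Character vector of neighbor symbols; never contains `gene`.
#' @export
neighbors <- function(net, gene) {
  stopifnot(inherits(net, "ppi_network"))
  gene <- toupper(trimws(gene))
  if (!gene %in% net$nodes)
    stop("gene not in network: ", gene)
  net$adjacency[[gene]]
}

#' Per-gene degree (connectivity) table
#'
#' @param net a [ppi_network].
#' @return Data frame with columns `gene` and `degree`; degrees sum to twice
#'   the number of edges.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  data.frame(gene = net$nodes,
             degree = vapply(net$adjacency, length, 1L)[net$nodes],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.ppi_network <- function(x, ...) {
  deg <- vapply(x$adjacency, length, 1L)
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (length(deg))
    cat(sprintf("  degree: median %g, max %d (%s)\n",
                stats::median(deg), max(deg), names(which.max(deg))))
  invisible(x)
}
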