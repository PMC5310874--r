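#' Area adjacency graph
#'
#' Undirected neighbourhood structure over the study areas, used to build the
#' intrinsic CAR (Besag) precision matrix.  Edges are stored deduplicated
#' with no self-loops; the number of connected components is computed on
#' construction because the ICAR precision has rank `n - c`.
#'
#' @param n_nodes Number of areas.
#' @param edges Two-column matrix (or data frame) of node indices in
#'   `1..n_nodes`, one row per undirected edge.  May be empty.
#' @param labels Optional character vector of area names (defaults to
#'   `"1".."n"`); must align with the `area` labels of any
#'   [mortality_dataset()] the graph is paired with.
#' @return An object of class `adjacency_graph` with elements `n`, `edges`
#'   (normalised so `edges[,1] < edges[,2]`), `labels`, `n_components`,
#'   `components` (membership vector).
#' @export
adjacency_graph <- function(n_nodes, edges, labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("graph needs at least one node", call. = FALSE)
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n_nodes)) {
      stop("edge refers to unknown node id", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (is.null(labels)) labels <- as.character(seq_len(n_nodes))
  if (length(labels) != n_nodes) {
    stop("labels must have one entry per node", call. = FALSE)
  }
  g <- igraph::make_graph(t(edges), n = n_nodes, directed = FALSE)
  comp <- igraph::components(g)
  structure(
    list(n = n_nodes, edges = edges, labels = as.character(labels),
         n_components = comp$no, components = as.integer(comp$membership)),
    class = "adjacency_graph"
  )
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d nodes, %d edges, %d connected component(s)\n",
              x$n, nrow(x$edges), x$n_components))
  invisible(x)
}

#' Read an adjacency graph from a file
#'
#' Two dialects are supported.  An *edge list* (`.edges`) has one `u v` pair
#' per line, where `u`, `v` are 1-based node indices; an optional first line
#' `n <N>` declares the node count (otherwise the maximum index is used, so
#' trailing isolated nodes need the declaration).  A *region file*
#' (`.graph`, the format used by spatial-epidemiology software) starts with
#' the node count and then has one line per region:
#' `region n_neighbours neighbour...`.
#'
#' @param path Path to the graph file.  The dialect is chosen by extension
#'   (`.graph` means region format) with a fallback: if the first line is a
#'   single integer, region format is assumed.
#' @param labels Optional node labels.
#' @return An [adjacency_graph()].
#' @export
load_graph <- function(path, labels = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty graph file", call. = FALSE)
  toks1 <- strsplit(lines[1], "\\s+")[[1]]
  region_style <- grepl("\\.graph$", path) || length(toks1) == 1L
  if (region_style) {
    n <- as.integer(toks1[1])
    if (is.na(n)) stop("region file must start with the node count", call. = FALSE)
    edges <- list()
    for (ln in lines[-1]) {
      tok <- as.integer(strsplit(ln, "\\s+")[[1]])
      if (anyNA(tok) || length(tok) < 2) {
        stop(sprintf("malformed region line: '%s'", ln), call. = FALSE)
      }
      region <- tok[1]; nn <- tok[2]; nbrs <- tok[-(1:2)]
      if (length(nbrs) != nn) {
        stop(sprintf("region %d declares %d neighbours but lists %d",
                     region, nn, length(nbrs)), call. = FALSE)
      }
      if (nn > 0) edges[[length(edges) + 1L]] <- cbind(region, nbrs)
    }
    edges <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  } else {
    n <- NA_integer_
    if (identical(toks1[1], "n")) {
      n <- as.integer(toks1[2])
      lines <- lines[-1]
    }
    pairs <- lapply(lines, function(ln) as.integer(strsplit(ln, "\\s+")[[1]]))
    if (any(vapply(pairs, length, 1L) != 2L) || anyNA(unlist(pairs))) {
      stop("edge list lines must each hold two integer node ids", call. = FALSE)
    }
    edges <- do.call(rbind, pairs)
    if (is.na(n)) n <- if (nrow(edges)) max(edges) else 1L
  }
  adjacency_graph(n_nodes = n, edges = edges, labels = labels)
}

#' Write an adjacency graph
#'
#' @param graph An [adjacency_graph()].
#' @param path Output path.
#' @param format `"edges"` (edge list with an `n` header line) or `"region"`
#'   (node count then region/neighbour lines).
#' @export
write_graph <- function(graph, path, format = c("edges", "region")) {
  format <- match.arg(format)
  if (format == "edges") {
    lines <- c(sprintf("n %d", graph$n),
               apply(graph$edges, 1, paste, collapse = " "))
  } else {
    nbr <- lapply(seq_len(graph$n), function(v) {
      sort(c(graph$edges[graph$edges[, 1] == v, 2],
             graph$edges[graph$edges[, 2] == v, 1]))
    })
    lines <- c(as.character(graph$n),
               vapply(seq_len(graph$n), function(v) {
                 paste(c(v, length(nbr[[v]]), nbr[[v]]), collapse = " ")
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Rook-adjacency lattice graph
#'
#' Regular `rows x cols` lattice with horizontal and vertical neighbours,
#' used as a stand-in for real administrative adjacency (a 5 x 10 lattice
#' has 50 nodes, matching the number of Spanish provinces, and
#' `2*r*c - r - c = 85` edges).
#'
#' @param rows,cols Lattice dimensions (both at least 1).
#' @return An [adjacency_graph()].
#' @export
lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("lattice dimensions must be >= 1", call. = FALSE)
  id <- function(r, c) (r - 1L) * cols + c
  edges <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges[[length(edges) + 1L]] <- c(id(r, c), id(r, c + 1L))
    if (r < rows) edges[[length(edges) + 1L]] <- c(id(r, c), id(r + 1L, c))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  adjacency_graph(rows * cols, edges)
}
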