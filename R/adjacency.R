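#' Areal adjacency graph
#'
#' A symmetric, binary neighbourhood structure over tracts: for each tract the
#' set of its neighbours and its neighbour count.  This is the spatial
#' skeleton behind the ICAR prior and Moran's I.
#'
#' @param neighbors list of integer vectors; `neighbors[[i]]` holds the
#'   indices of the neighbours of tract `i`.  Must be symmetric and free of
#'   self-loops.
#' @param ids character vector of tract identifiers (unique), one per tract.
#' @param warn_islands warn when a tract has no neighbours (default `TRUE`).
#'   Islands are permitted; the sampler pins their spatial effect at zero.
#'
#' @return An object of class `adjacency_graph`: a list with elements
#'   `nb` (list of sorted integer neighbour vectors), `ids`, `n`,
#'   `degree` (the neighbour counts) and `component` (connected-component
#'   membership, islands being singleton components).
#' @export
adjacency_graph <- function(neighbors, ids = NULL, warn_islands = TRUE) {
  n <- length(neighbors)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal length(neighbors)")
  if (anyDuplicated(ids)) stop("duplicated tract ids in adjacency graph")
  nb <- lapply(neighbors, function(x) sort(unique(as.integer(x))))
  for (i in seq_len(n)) {
    x <- nb[[i]]
    if (length(x) && (min(x) < 1L || max(x) > n))
      stop("neighbor index out of range for tract ", ids[i])
    if (i %in% x) stop("self-neighbor listed for tract ", ids[i])
    for (j in x) {
      if (!(i %in% nb[[j]]))
        stop("asymmetric adjacency: ", ids[i], " lists ", ids[j],
             " but not vice versa")
    }
  }
  deg <- vapply(nb, length, integer(1))
  if (warn_islands && any(deg == 0L))
    warning(sum(deg == 0L), " island tract(s) with no neighbors: ",
            paste(ids[deg == 0L], collapse = ", "))
  g <- structure(list(nb = nb, ids = ids, n = n, degree = deg),
                 class = "adjacency_graph")
  g$component <- graph_components(g)
  g
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph: ", x$n, " tracts, ",
      sum(x$degree) / 2, " edges, ",
      max(x$component), " connected component(s)\n", sep = "")
  cat("degree range: [", min(x$degree), ", ", max(x$degree), "]\n", sep = "")
  invisible(x)
}

#' Connected components of an adjacency graph
#'
#' Breadth-first labelling; islands form singleton components.  Component
#' structure matters because the ICAR prior is improper per component and the
#' sum-to-zero constraint is applied within each one.
#'
#' @param graph an `adjacency_graph` (or a bare list with `nb` and `n`).
#' @return integer vector of component labels `1..k`.
#' @export
graph_components <- function(graph) {
  n <- graph$n
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in graph$nb[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- k
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Greedy vertex colouring; within a colour class no two tracts are adjacent,
# so single-site updates of the spatial effect can be vectorised per class.
graph_coloring <- function(graph) {
  n <- graph$n
  col <- integer(n)
  for (i in order(graph$degree, decreasing = TRUE)) {
    used <- col[graph$nb[[i]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    col[i] <- c0
  }
  col
}

#' Read / write GAL adjacency files
#'
#' The GAL dialect used here is: a header line whose last token is the number
#' of areal units, then for each unit a line `id degree` followed by a line
#' listing the `degree` neighbour ids (the neighbour line is omitted or empty
#' for islands).
#'
#' @param path file path.
#' @param symmetrize if `TRUE`, a one-directional listing is completed to a
#'   symmetric graph instead of raising an error.
#' @return `read_gal()` returns an `adjacency_graph`; `write_gal()` returns
#'   `path` invisibly.  The round trip `read_gal(write_gal(g))` preserves the
#'   neighbour sets exactly.
#' @export
read_gal <- function(path, symmetrize = FALSE) {
  if (!file.exists(path)) stop("GAL file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GAL file: ", path)
  head_tok <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(head_tok[length(head_tok)]))
  if (is.na(n) || n < 0L) stop("malformed GAL header: ", lines[[1L]])
  ids <- character(n)
  raw_nb <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    if (pos > length(lines)) stop("truncated GAL file: ", path)
    tok <- strsplit(trimws(lines[[pos]]), "\\s+")[[1L]]
    if (length(tok) != 2L) stop("malformed GAL record line: ", lines[[pos]])
    ids[i] <- tok[[1L]]
    deg <- suppressWarnings(as.integer(tok[[2L]]))
    if (is.na(deg) || deg < 0L) stop("malformed degree in GAL record: ", lines[[pos]])
    pos <- pos + 1L
    if (deg > 0L) {
      if (pos > length(lines)) stop("truncated GAL file: ", path)
      nbr <- strsplit(trimws(lines[[pos]]), "\\s+")[[1L]]
      if (length(nbr) != deg)
        stop("GAL record for ", ids[i], " promises ", deg, " neighbors, lists ",
             length(nbr))
      raw_nb[[i]] <- nbr
      pos <- pos + 1L
    } else {
      raw_nb[[i]] <- character(0)
    }
  }
  if (anyDuplicated(ids)) stop("duplicated ids in GAL file: ", path)
  idx <- lapply(raw_nb, function(x) {
    m <- match(x, ids)
    if (anyNA(m)) stop("GAL file lists unknown neighbor id(s): ",
                       paste(x[is.na(m)], collapse = ", "))
    m
  })
  if (symmetrize) {
    for (i in seq_len(n)) for (j in idx[[i]])
      idx[[j]] <- union(idx[[j]], i)
  } else {
    for (i in seq_len(n)) for (j in idx[[i]])
      if (!(i %in% idx[[j]]))
        stop("asymmetric GAL listing: ", ids[i], " -> ", ids[j],
             " has no reverse entry (use symmetrize = TRUE to repair)")
  }
  adjacency_graph(idx, ids)
}

#' @rdname read_gal
#' @param graph an `adjacency_graph`.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(graph$n), con)
  for (i in seq_len(graph$n)) {
    writeLines(paste(graph$ids[i], graph$degree[i]), con)
    if (graph$degree[i] > 0L)
      writeLines(paste(graph$ids[graph$nb[[i]]], collapse = " "), con)
  }
  invisible(path)
}
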