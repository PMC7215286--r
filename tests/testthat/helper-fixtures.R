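# small in-code fixtures shared across test files

# n-tract table with C covariates, deterministic content
make_table <- function(n = 12, C = 2, seed = 1, counts = NULL, households = NULL) {
  set.seed(seed)
  x <- matrix(round(stats::runif(n * C), 4), n, C,
              dimnames = list(NULL, sprintf("ses_%02d", seq_len(C))))
  df <- data.frame(tract_id = sprintf("T%03d", seq_len(n)),
                   households = if (is.null(households))
                     sample(50:500, n, replace = TRUE) else households,
                   count = if (is.null(counts))
                     stats::rpois(n, 2) else counts,
                   x, check.names = FALSE)
  tract_table(df)
}

grid_graph <- function(rows, cols) {
  build_queen_adjacency(grid_polygons(rows, cols))
}

path_graph <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    intersect(c(i - 1L, i + 1L), seq_len(n)))
  adjacency_graph(nb, sprintf("P%02d", seq_len(n)))
}

# dense Laplacian of an adjacency graph
graph_laplacian <- function(g) {
  L <- matrix(0, g$n, g$n)
  for (i in seq_len(g$n)) L[i, g$nb[[i]]] <- -1
  diag(L) <- g$degree
  L
}

# quiet the small-n decile warning where it is expected and irrelevant
quiet_deciles <- function(expr) suppressWarnings(expr)
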