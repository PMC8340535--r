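#' Load a directed functional-interaction network from an edge table
#'
#' Reads a tab-separated edge table with columns `source`, `target`,
#' `directed` (0/1) and `type`, the dialect used for merged
#' gene/miRNA interaction networks (e.g. Kegg + Signor + miRTarBase exports).
#' Rows flagged `directed = 0` (typically "binding" or "complex"
#' interactions) are expanded into both orientations; self-interactions are
#' removed and duplicate (source, target) pairs are collapsed.
#'
#' @param edges Path to a TSV file, or a data.frame with the same columns.
#' @param expand_undirected Expand `directed = 0` rows into both directions
#'   (default `TRUE`). When `FALSE`, undirected rows contribute only their
#'   written orientation.
#' @return A `medinet_network` object: a list with `nodes` (character vector,
#'   lexicographic order), `edges` (data.frame of 1-based `from`/`to` node
#'   indices and `type`), and `kind` (named character vector, `"gene"` or
#'   `"mirna"` per node).
#' @details Node order is deterministic (lexicographic by id, `LC_COLLATE=C`),
#'   so repeated loads of the same table yield identical objects. miRNA nodes
#'   are recognised by the conventional `miR`/`let-`/`mir` id prefixes
#'   (optionally preceded by a species tag such as `mmu-`).
#' @seealso [largest_scc()], [transition_matrix()], [diffusion_operator()]
#' @export
load_network <- function(edges, expand_undirected = TRUE) {
  if (is.character(edges)) {
    if (!file.exists(edges)) stop("edge table not found: ", edges)
    edges <- data.table::fread(edges, sep = "\t", header = TRUE,
                               colClasses = list(character = c("source", "target")),
                               data.table = FALSE)
  }
  required <- c("source", "target", "directed", "type")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0L) {
    stop("edge table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(edges) == 0L) stop("edge table is empty: no interactions to load")
  src <- trimws(as.character(edges$source))
  tgt <- trimws(as.character(edges$target))
  if (any(src == "") || any(tgt == "")) stop("edge table contains empty node ids")
  dir_flag <- as.integer(edges$directed)
  if (any(is.na(dir_flag)) || !all(dir_flag %in% c(0L, 1L))) {
    stop("column 'directed' must be 0 or 1")
  }
  type <- as.character(edges$type)

  if (expand_undirected) {
    undir <- dir_flag == 0L
    src0 <- src; tgt0 <- tgt
    src <- c(src0, tgt0[undir])
    tgt <- c(tgt0, src0[undir])
    type <- c(type, type[undir])
  }
  keep <- src != tgt                      # drop self-interactions
  src <- src[keep]; tgt <- tgt[keep]; type <- type[keep]
  if (length(src) == 0L) stop("network has no edges after removing self-interactions")

  nodes <- sort(unique(c(src, tgt)), method = "radix")
  from <- match(src, nodes)
  to <- match(tgt, nodes)
  dup <- duplicated(cbind(from, to))
  edge_df <- data.frame(from = from[!dup], to = to[!dup],
                        type = type[!dup], stringsAsFactors = FALSE)
  ord <- order(edge_df$from, edge_df$to)
  edge_df <- edge_df[ord, , drop = FALSE]
  rownames(edge_df) <- NULL

  new_network(nodes, edge_df)
}

new_network <- function(nodes, edge_df) {
  kind <- ifelse(grepl("^([a-z]{3}-)?(mir|let)", tolower(nodes)), "mirna", "gene")
  names(kind) <- nodes
  structure(list(nodes = nodes, edges = edge_df, kind = kind),
            class = "medinet_network")
}

#' @export
print.medinet_network <- function(x, ...) {
  cat(sprintf("medinet_network: %d nodes (%d genes, %d miRNAs), %d directed edges\n",
              length(x$nodes), sum(x$kind == "gene"), sum(x$kind == "mirna"),
              nrow(x$edges)))
  invisible(x)
}

#' Construct a network directly from an edge data.frame of node ids
#'
#' Convenience constructor used by the simulator and tests: takes character
#' `from`/`to` columns that are already directed and builds the canonical
#' `medinet_network` representation (self-edges dropped, duplicates collapsed,
#' nodes ordered lexicographically).
#'
#' @param from,to Character vectors of source and target node ids.
#' @param type Optional edge type tags (recycled).
#' @return A `medinet_network`.
#' @export
network_from_edges <- function(from, to, type = "interaction") {
  load_network(data.frame(source = from, target = to, directed = 1L,
                          type = type, stringsAsFactors = FALSE),
               expand_undirected = FALSE)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$nodes[net$edges$from], to = net$nodes[net$edges$to]),
    directed = TRUE,
    vertices = data.frame(name = net$nodes))
}

#' Restrict a network to its largest strongly connected component
#'
#' Diffusion on a directed graph has a unique, well-behaved steady state only
#' when every node can reach every other node, so scoring is performed on the
#' largest strongly connected component (SCC) of the interaction network.
#' Ties in component size are broken by keeping the component containing the
#' lexicographically smallest node id.
#'
#' @param net A `medinet_network`.
#' @return The induced `medinet_network` on the largest SCC.
#' @export
largest_scc <- function(net) {
  stopifnot(inherits(net, "medinet_network"))
  comp <- igraph::components(as_igraph(net), mode = "strong")
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # keep the component whose smallest member id sorts first
    firsts <- vapply(biggest, function(ci) min(net$nodes[comp$membership == ci]),
                     character(1))
    biggest <- biggest[order(firsts)[1L]]
  }
  keep <- which(comp$membership == biggest)
  induced_network(net, keep)
}

induced_network <- function(net, keep_idx) {
  nodes <- net$nodes[sort(keep_idx)]
  old_in <- net$edges$from %in% sort(keep_idx) & net$edges$to %in% sort(keep_idx)
  e <- net$edges[old_in, , drop = FALSE]
  remap <- match(net$nodes, nodes)
  e$from <- remap[e$from]
  e$to <- remap[e$to]
  rownames(e) <- NULL
  new_network(nodes, e)
}

#' Reverse every edge of a network
#'
#' Used to build the backward diffusion operator: signal flows from downstream
#' molecular evidence back toward candidate mediators along reversed edges.
#' Reversal happens before row-normalisation, which is not equivalent to
#' transposing the forward operator.
#'
#' @param net A `medinet_network`.
#' @return A `medinet_network` with all edges reversed.
#' @export
reverse_network <- function(net) {
  stopifnot(inherits(net, "medinet_network"))
  e <- data.frame(from = net$edges$to, to = net$edges$from,
                  type = net$edges$type, stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new_network(net$nodes, e)
}

#' Build the row-stochastic transition matrix of a network
#'
#' `W[i, j] = 1 / outdegree(i)` for every edge `i -> j`: a random walker at
#' node `i` moves to a uniformly chosen out-neighbour. A column-stochastic
#' variant (normalising by in-degree of the target) is available behind
#' `orientation = "column"` for sensitivity analyses.
#'
#' @param net A `medinet_network` in which every node has out-degree >= 1
#'   (guaranteed after [largest_scc()] on a graph with >= 2 nodes).
#' @param orientation `"row"` (default) or `"column"`.
#' @return A sparse `dgCMatrix` with node ids as dimnames.
#' @export
transition_matrix <- function(net, orientation = c("row", "column")) {
  stopifnot(inherits(net, "medinet_network"))
  orientation <- match.arg(orientation)
  n <- length(net$nodes)
  from <- net$edges$from
  to <- net$edges$to
  if (orientation == "row") {
    deg <- tabulate(from, nbins = n)
    zero <- which(deg == 0L)
    if (length(zero) > 0L) {
      stop("node(s) with out-degree 0 cannot be row-normalised: ",
           paste(utils::head(net$nodes[zero], 5L), collapse = ", "))
    }
    x <- 1 / deg[from]
  } else {
    deg <- tabulate(to, nbins = n)
    zero <- which(deg == 0L)
    if (length(zero) > 0L) {
      stop("node(s) with in-degree 0 cannot be column-normalised: ",
           paste(utils::head(net$nodes[zero], 5L), collapse = ", "))
    }
    x <- 1 / deg[to]
  }
  Matrix::sparseMatrix(i = from, j = to, x = x, dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

#' Insulated diffusion operator (random walk with restart)
#'
#' Computes `F = beta * (I - (1 - beta) * W)^-1` for a row-stochastic
#' transition matrix `W` and restart probability `beta`. Row `i` of `F` is the
#' stationary distribution of a walk that starts at node `i` and restarts
#' there with probability `beta` at each step; it distributes node `i`'s
#' signal over its reachable neighbourhood with geometric decay.
#'
#' @param W Row-stochastic transition matrix from [transition_matrix()].
#' @param beta Restart probability in (0, 1]. Larger values keep the signal
#'   more local; `beta = 1` is no diffusion at all (`F = I`).
#' @param method `"auto"` (dense direct solve up to 3000 nodes, power-series
#'   iteration above), `"direct"`, or `"series"`.
#' @param tol Convergence tolerance for the power-series method (max-abs
#'   difference between successive partial sums).
#' @return A `medinet_diffusion` object: list with dense matrix `F` (dimnames
#'   = node ids) and `beta`.
#' @details Every row of `F` sums to 1 and all entries are non-negative;
#'   diagonal entries are at least `beta`. The matrix is checked for row-sum
#'   conservation to 1e-9 before being returned.
#' @export
diffusion_operator <- function(W, beta = 0.4, method = c("auto", "direct", "series"),
                               tol = 1e-12) {
  method <- match.arg(method)
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta <= 0 || beta > 1) {
    stop("beta must be a single number in (0, 1]")
  }
  n <- nrow(W)
  if (method == "auto") method <- if (n <= 3000L) "direct" else "series"
  if (method == "direct") {
    A <- diag(n) - (1 - beta) * as.matrix(W)
    Fm <- beta * solve(A)
  } else {
    # F = beta * sum_k ((1-beta) W)^k; accumulate row-wise via sparse products
    Wd <- Matrix::drop0(W)
    term <- Matrix::Diagonal(n)
    Fm <- matrix(0, n, n)
    fac <- 1
    for (k in seq_len(100000L)) {
      Fm <- Fm + beta * fac * as.matrix(term)
      fac <- fac * (1 - beta)
      term <- term %*% Wd
      if (fac < tol) break
    }
  }
  dimnames(Fm) <- dimnames(W)
  rs <- rowSums(Fm)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("diffusion operator rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), "); W may not be row-stochastic")
  }
  structure(list(F = Fm, beta = beta), class = "medinet_diffusion")
}

#' @export
print.medinet_diffusion <- function(x, ...) {
  cat(sprintf("medinet_diffusion: %d x %d operator, beta = %g\n",
              nrow(x$F), ncol(x$F), x$beta))
  invisible(x)
}

#' Build forward and backward diffusion operators for a network
#'
#' Convenience wrapper producing the operator pair consumed by
#' [sample_scores()]: one operator on the network as given (upstream events
#' diffuse forward) and one on the edge-reversed network (downstream evidence
#' diffuses backward).
#'
#' @inheritParams diffusion_operator
#' @param net A strongly connected `medinet_network`.
#' @return List with elements `fwd` and `rev` (both `medinet_diffusion`).
#' @export
diffusion_operators <- function(net, beta = 0.4, method = "auto") {
  list(fwd = diffusion_operator(transition_matrix(net), beta = beta, method = method),
       rev = diffusion_operator(transition_matrix(reverse_network(net)),
                                beta = beta, method = method))
}
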