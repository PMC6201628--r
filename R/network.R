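# Protein-protein interaction network and the two-step degree-normalised
# diffusion that turns an initial signed perturbation into a final signature.

#' Build an undirected PPI network from an edge list
#'
#' Constructs a simple undirected graph over gene symbols. Duplicate edges
#' (including reversed duplicates) are collapsed and self-loops are dropped
#' with a message. Node order is fixed at construction (first appearance in
#' the edge list) and is used for all matrix-form computations.
#'
#' @param edges A two-column character matrix or data frame of gene pairs,
#'   e.g. the result of [read_network_edges()].
#' @return An object of class `ppi_network`: a list with elements
#'   `nodes` (character vector, fixed order), `adj` (sparse symmetric 0/1
#'   adjacency with zero diagonal) and `degree` (named integer vector).
#' @examples
#' net <- build_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' net$degree
#' @export
build_network <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(dim(edges)) || ncol(edges) < 2L || nrow(edges) == 0L) {
    stop("'edges' must be a non-empty two-column edge list")
  }
  from <- as.character(edges[, 1L])
  to <- as.character(edges[, 2L])

  # node order = first appearance, interleaving the two columns row by row;
  # fixed before loop-dropping so a self-loop-only node survives (isolated)
  nodes <- unique(as.vector(rbind(from, to)))

  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0L) stop("no edges remain after dropping self-loops")
  n <- length(nodes)
  i <- match(from, nodes)
  j <- match(to, nodes)

  # collapse duplicate and reversed-duplicate edges
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]
  hi <- hi[keep]

  adj <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  deg <- as.integer(Matrix::rowSums(adj))
  names(deg) <- nodes

  structure(
    list(nodes = nodes, adj = adj, degree = deg, n_edges = length(lo)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "nodes,", x$n_edges, "edges\n")
  invisible(x)
}

# Expand a sparse (named, possibly partial) perturbation vector to the full
# node order of the network. Errors on genes outside the network.
.full_vector <- function(network, v) {
  if (is.null(names(v))) {
    if (length(v) != length(network$nodes)) {
      stop("unnamed perturbation vector must cover all network nodes")
    }
    names(v) <- network$nodes
    return(v)
  }
  miss <- setdiff(names(v), network$nodes)
  if (length(miss) > 0L) {
    stop(
      "perturbation genes absent from the network: ",
      paste(utils::head(miss, 10L), collapse = ", "),
      if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L)
    )
  }
  x <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  x[names(v)] <- v
  x
}

.stage_of <- function(v) {
  s <- attr(v, "stage")
  if (is.null(s)) "initial" else s
}

.next_stage <- function(stage) {
  switch(stage, initial = "step1", step1 = "step2", step2 = "step3", "later")
}

#' One step of degree-normalised network diffusion
#'
#' Each node i sends `c_i / D_i` to every one of its `D_i` neighbours, so the
#' value arriving at node j is the sum of `c_i / D_i` over its neighbours.
#' Nodes with degree zero contribute nothing (their `c_i / D_i` term is
#' defined as 0) and, by symmetry, receive nothing; any mass they carried is
#' lost, which is reported with a warning.
#'
#' @param network A `ppi_network` from [build_network()].
#' @param v Named numeric perturbation vector; names must be network nodes.
#'   May cover only a subset of nodes (missing nodes are 0).
#' @return Named numeric vector over all network nodes, with attribute
#'   `stage` advanced by one (`initial` -> `step1` -> `step2`).
#' @seealso [diffuse_two_step()] for the full two-step model.
#' @export
diffuse_step <- function(network, v) {
  stopifnot(inherits(network, "ppi_network"))
  x <- .full_vector(network, v)
  if (any(!is.finite(x))) stop("perturbation vector contains non-finite values")
  deg <- network$degree
  iso <- deg == 0L
  if (any(iso & x != 0)) {
    warning(
      "mass lost at isolated node(s): ",
      format(sum(abs(x[iso]))), " absolute intensity"
    )
  }
  xd <- numeric(length(x))
  xd[!iso] <- x[!iso] / deg[!iso]
  out <- as.numeric(network$adj %*% xd)
  names(out) <- network$nodes
  attr(out, "stage") <- .next_stage(.stage_of(v))
  out
}

#' Two-step diffusion: the final perturbation signature
#'
#' Applies [diffuse_step()] twice. The result is the final perturbation
#' signature of an ingredient, herb or herbal combination over the network:
#' `(A D^-1)^2 c` in matrix form, where `A` is the adjacency matrix and `D`
#' the diagonal degree matrix.
#'
#' @inheritParams diffuse_step
#' @return Named numeric vector over all network nodes, stage `step2`.
#' @examples
#' net <- build_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' diffuse_two_step(net, c(A = 1))
#' @export
diffuse_two_step <- function(network, v) {
  out <- diffuse_step(network, diffuse_step(network, v))
  attr(out, "stage") <- "step2"
  out
}

#' Write a final signature as a two-column TSV
#'
#' Genes are written in descending intensity order (ties broken by ascending
#' gene symbol).
#'
#' @param v Named numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(v, path) {
  ord <- order(-v, names(v), method = "radix")
  df <- data.frame(gene = names(v)[ord], intensity = unname(v[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
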