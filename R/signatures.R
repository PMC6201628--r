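# Signed initial signatures for ingredients, herbs and combinations;
# extreme-gene signature extraction; disease-profile construction.

#' Initial perturbation signature of one ingredient
#'
#' The initial signature assigns +1 to every target the ingredient activates
#' and -1 to every target it inhibits. Duplicate (gene, mode) rows collapse
#' to a single entry; two different modes for the same gene within one
#' ingredient are contradictory and raise an error.
#'
#' @param genes Character vector of target gene symbols.
#' @param modes Integer vector of +1 / -1, same length.
#' @param id Optional ingredient id (used in error messages).
#' @return Named numeric vector (stage `initial`).
#' @export
ingredient_signature <- function(genes, modes, id = NULL) {
  genes <- as.character(genes)
  modes <- as.numeric(modes)
  if (length(genes) != length(modes)) stop("genes and modes differ in length")
  if (!all(modes %in% c(-1, 1))) stop("modes must be +1 or -1")
  keep <- !duplicated(paste(genes, modes))
  genes <- genes[keep]
  modes <- modes[keep]
  if (anyDuplicated(genes)) {
    g <- genes[duplicated(genes)][1L]
    stop("conflicting modes for gene ", g,
         if (!is.null(id)) paste0(" in ingredient ", id))
  }
  v <- stats::setNames(modes, genes)
  attr(v, "stage") <- "initial"
  v
}

# Genewise weighted sum of named numeric vectors.
.superpose <- function(vectors, weights) {
  genes <- unique(unlist(lapply(vectors, names), use.names = FALSE))
  out <- stats::setNames(numeric(length(genes)), genes)
  for (k in seq_along(vectors)) {
    v <- vectors[[k]]
    out[names(v)] <- out[names(v)] + weights[k] * v
  }
  attr(out, "stage") <- "initial"
  out
}

#' Initial perturbation signature of a herb
#'
#' The herb signature is the superposition (genewise sum) of its
#' ingredients' signatures. An ingredient with known content contributes
#' with weight equal to its content fraction; an ingredient with unknown
#' content contributes with weight 1. A herb mixing known and unknown
#' contents therefore mixes scales; this is flagged with a message.
#'
#' @param ingredients List of ingredient signatures (named numeric vectors).
#' @param contents Numeric vector of content fractions in (0, 1], `NA` for
#'   unknown; recycled `NA` if omitted.
#' @return Named numeric vector (stage `initial`).
#' @export
herb_signature <- function(ingredients, contents = NULL) {
  if (length(ingredients) == 0L) stop("herb has no ingredients")
  if (is.null(contents)) contents <- rep(NA_real_, length(ingredients))
  if (length(contents) != length(ingredients)) {
    stop("contents and ingredients differ in length")
  }
  known <- !is.na(contents)
  if (any(known) && any(contents[known] <= 0 | contents[known] > 1)) {
    stop("content fractions must lie in (0, 1]")
  }
  if (any(known) && any(!known)) {
    message("herb mixes known and unknown ingredient contents; ",
            "unknown contents weighted 1")
  }
  w <- ifelse(known, contents, 1)
  .superpose(ingredients, w)
}

#' Initial perturbation signature of a herbal combination
#'
#' Superposition of the member herbs' signatures, by default unweighted.
#' The result does not depend on the order herbs are listed.
#'
#' @param herbs List of herb signatures (named numeric vectors).
#' @param weights Per-herb weights, default all 1.
#' @return Named numeric vector (stage `initial`).
#' @export
combination_signature <- function(herbs, weights = NULL) {
  if (length(herbs) == 0L) stop("combination has no herbs")
  if (is.null(weights)) weights <- rep(1, length(herbs))
  if (length(weights) != length(herbs)) stop("weights and herbs differ in length")
  .superpose(herbs, weights)
}

#' Final perturbation signature over the network
#'
#' Restricts the initial signature to network nodes (dropping out-of-network
#' targets with a message) and applies the two-step diffusion. The output is
#' the final perturbation signature used for extreme-gene extraction and
#' herb-disease matching.
#'
#' @param network A `ppi_network`.
#' @param initial Named numeric initial signature.
#' @return Named numeric vector over all network nodes, stage `step2`.
#' @export
final_signature <- function(network, initial) {
  inside <- names(initial) %in% network$nodes
  if (!all(inside)) {
    message(sum(!inside), " target(s) outside the network dropped")
    initial <- initial[inside]
  }
  if (length(initial) == 0L) {
    stop("no targets remain inside the network")
  }
  diffuse_two_step(network, initial)
}

#' Build all herb initial signatures from a herb library table
#'
#' Groups the library by herb, builds each ingredient's signed signature and
#' superposes them with the content-weight rule of [herb_signature()].
#' Conflicting modes for one gene across different ingredients of the same
#' herb are allowed and simply sum (they may cancel); conflicts within a
#' single ingredient are errors.
#'
#' @param library Herb library data frame (see [read_herb_library()]).
#' @return Named list of initial signatures, one per herb id.
#' @export
herb_initial_signatures <- function(library) {
  library <- validate_herb_library(library)
  out <- list()
  for (h in unique(library$herb_id)) {
    sub <- library[library$herb_id == h, , drop = FALSE]
    ings <- list()
    contents <- numeric(0)
    for (ing in unique(sub$ingredient_id)) {
      rows <- sub[sub$ingredient_id == ing, , drop = FALSE]
      ings[[ing]] <- ingredient_signature(rows$target_gene, rows$mode, id = ing)
      # content is a property of the (herb, ingredient) pair; take the first
      contents <- c(contents, rows$content[1L])
    }
    out[[h]] <- suppressMessages(herb_signature(ings, contents))
  }
  out
}

#' Final signatures for every herb in a library
#'
#' @param library Herb library data frame.
#' @param network A `ppi_network`.
#' @return Numeric matrix, network nodes x herbs, each column a final
#'   signature.
#' @export
herb_final_signatures <- function(library, network) {
  inits <- herb_initial_signatures(library)
  mat <- matrix(0, nrow = length(network$nodes), ncol = length(inits),
                dimnames = list(network$nodes, names(inits)))
  for (k in seq_along(inits)) {
    mat[, k] <- suppressMessages(final_signature(network, inits[[k]]))
  }
  mat
}

#' Extreme-gene signature of a final perturbation vector
#'
#' Takes the `t` most positively and `t` most negatively perturbed genes.
#' The vector is ordered once by descending intensity with ties broken by
#' ascending gene symbol; the top set is the head and the bottom set the
#' tail of that single ordering, which guarantees the two sets are disjoint
#' whenever at least `2t` genes are available.
#'
#' @param v Named numeric final signature.
#' @param t Set size (default 250).
#' @param id Signature identifier.
#' @return Object of class `extreme_signature`: list with `top`, `bottom`,
#'   `t`, `id`.
#' @export
extreme_signature <- function(v, t = 250, id = "signature") {
  t <- as.integer(t)
  if (t < 1L) stop("t must be a positive integer")
  v <- v[is.finite(v)]
  if (length(v) < 2L * t) {
    stop("need at least ", 2L * t, " genes for t = ", t,
         "; only ", length(v), " available")
  }
  ord <- order(-v, names(v), method = "radix")
  g <- names(v)[ord]
  extreme_signature_sets(g[seq_len(t)], rev(g)[seq_len(t)], id = id)
}

#' Construct an extreme signature from explicit gene sets
#' @param top,bottom Character vectors of equal length with no overlap.
#' @param id Signature identifier.
#' @return An `extreme_signature` object.
#' @export
extreme_signature_sets <- function(top, bottom, id = "signature") {
  top <- as.character(top)
  bottom <- as.character(bottom)
  if (length(top) != length(bottom)) {
    stop("top and bottom sets must have equal size")
  }
  if (length(top) == 0L) stop("extreme sets must be non-empty")
  if (anyDuplicated(top) || anyDuplicated(bottom)) {
    stop("duplicate genes within an extreme set")
  }
  if (length(intersect(top, bottom)) > 0L) {
    stop("top and bottom sets overlap: ",
         paste(utils::head(intersect(top, bottom), 5L), collapse = ", "))
  }
  structure(list(top = top, bottom = bottom, t = length(top), id = id),
            class = "extreme_signature")
}

#' @export
print.extreme_signature <- function(x, ...) {
  cat("Extreme signature '", x$id, "': t = ", x$t, "\n", sep = "")
  invisible(x)
}

#' Jaccard distance between two gene sets
#'
#' `1 - |a intersect b| / |a union b|`. Used to quantify how much the
#' extreme-gene signatures of different herbs (or of the ingredients within
#' one herb) overlap.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("Jaccard distance undefined for two empty sets")
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Collapse a probe-level statistics table to gene level
#'
#' For each gene, keeps the row of the probe with the minimum p-value; ties
#' are broken by larger absolute fold change, then by probe id.
#'
#' @param stats Data frame with columns `probe_id`, `gene`, `p_value`,
#'   `fold_change`.
#' @return Data frame with columns `gene`, `fold_change`, one row per gene.
#' @export
collapse_probes <- function(stats) {
  need <- c("probe_id", "gene", "p_value", "fold_change")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(stats$probe_id)) stop("duplicate probe id(s)")
  if (any(stats$p_value < 0 | stats$p_value > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  ord <- order(stats$gene, stats$p_value, -abs(stats$fold_change),
               stats$probe_id, method = "radix")
  s <- stats[ord, , drop = FALSE]
  s <- s[!duplicated(s$gene), , drop = FALSE]
  out <- data.frame(gene = s$gene, fold_change = s$fold_change)
  rownames(out) <- NULL
  out
}

#' Build a ranked disease profile from a gene-level fold-change table
#' @param gene_fc Data frame with columns `gene`, `fold_change`.
#' @param id Optional profile identifier.
#' @return A [ranked_profile()].
#' @export
build_disease_profile <- function(gene_fc, id = NULL) {
  ranked_profile(gene_fc$gene, gene_fc$fold_change, id = id)
}
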