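# Seeded generators for networks, herb libraries, disease profiles and
# planted ground-truth fixtures, so every pipeline stage can be exercised
# without any external database.

#' Generate a synthetic interaction network
#'
#' Draws a simple undirected graph over synthetic gene symbols (`G0001`,
#' `G0002`, ...), either uniform-random (fixed edge count) or
#' preferential-attachment (degree-heterogeneous, the shape typical of
#' protein-interaction networks). Components are reconnected so the result
#' has no isolated nodes and is connected; all randomness is seeded.
#'
#' @param n_nodes Number of nodes (>= 3; default 300).
#' @param model `"preferential"` (default) or `"random"`.
#' @param edges_per_node Average edges added per node (default 4; curated
#'   protein-interaction networks are denser still, with mean degree around
#'   20, and overly sparse graphs leave two-step signatures degenerate).
#' @param seed Integer seed.
#' @return A `ppi_network`.
#' @export
make_network <- function(n_nodes = 300, model = c("preferential", "random"),
                         edges_per_node = 4, seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 3L) stop("n_nodes must be at least 3")
  if (edges_per_node < 1) stop("edges_per_node below 1 yields no usable graph")
  withr::with_seed(seed, {
    g <- if (model == "preferential") {
      igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
    } else {
      igraph::sample_gnm(n_nodes, m = round(edges_per_node * n_nodes))
    }
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      # re-attach every smaller component to the largest one
      giant <- which.max(comp$csize)
      anchor <- which(comp$membership == giant)[1L]
      extra <- vapply(
        setdiff(seq_len(comp$no), giant),
        function(cl) c(anchor, which(comp$membership == cl)[1L]),
        numeric(2)
      )
      g <- igraph::add_edges(g, as.vector(extra))
    }
    el <- igraph::as_edgelist(g)
    labels <- sprintf("G%04d", seq_len(n_nodes))
    build_network(cbind(labels[el[, 1L]], labels[el[, 2L]]))
  })
}

#' Generate a synthetic herb library table
#'
#' Emulates the herb / ingredient / target structure of a curated herb
#' library at desk scale: each herb holds a random number of ingredients,
#' each ingredient a random number of targets sampled from the network
#' nodes, with modes +1 (activated) at the given fraction and -1
#' (inhibited) otherwise. Targets are sampled without replacement within an
#' ingredient, so within-ingredient mode conflicts cannot occur.
#'
#' @param network A `ppi_network` supplying the target universe.
#' @param n_herbs Number of herbs (default 30).
#' @param ingredients_per_herb Integer range `c(min, max)` (default 2..5).
#' @param targets_per_ingredient Integer range `c(min, max)` (default 3..10).
#' @param activation_fraction Probability a target mode is +1 (default 0.5).
#' @param content_fraction Fraction of ingredients with a known content
#'   value drawn uniformly from (0, 1] (default 0: all contents unknown).
#' @param seed Integer seed.
#' @return Herb library data frame (see [read_herb_library()]).
#' @export
make_herb_library <- function(network, n_herbs = 30,
                              ingredients_per_herb = c(2, 5),
                              targets_per_ingredient = c(3, 10),
                              activation_fraction = 0.5,
                              content_fraction = 0, seed = 1L) {
  stopifnot(inherits(network, "ppi_network"), n_herbs >= 1)
  nodes <- network$nodes
  if (targets_per_ingredient[2L] > length(nodes)) {
    stop("targets_per_ingredient exceeds the number of network nodes")
  }
  if (ingredients_per_herb[1L] < 1L || targets_per_ingredient[1L] < 1L) {
    stop("ranges must start at 1 or above")
  }
  withr::with_seed(seed, {
    rows <- list()
    ing_counter <- 0L
    for (h in seq_len(n_herbs)) {
      herb_id <- sprintf("herb_%03d", h)
      n_ing <- sample(seq(ingredients_per_herb[1L], ingredients_per_herb[2L]), 1L)
      for (i in seq_len(n_ing)) {
        ing_counter <- ing_counter + 1L
        ing_id <- sprintf("ing_%05d", ing_counter)
        n_tgt <- sample(seq(targets_per_ingredient[1L],
                            targets_per_ingredient[2L]), 1L)
        targets <- sample(nodes, n_tgt)
        modes <- ifelse(stats::runif(n_tgt) < activation_fraction, 1L, -1L)
        content <- if (stats::runif(1) < content_fraction) {
          stats::runif(1, min = .Machine$double.eps, max = 1)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          herb_id = herb_id, ingredient_id = ing_id, target_gene = targets,
          mode = modes, content = content, stringsAsFactors = FALSE
        )
      }
    }
    validate_herb_library(do.call(rbind, rows))
  })
}

#' Disease profile with a planted reversal herb
#'
#' Builds a disease-pathological state profile whose ranking is the
#' negation of a herb's final perturbation signature plus Gaussian noise:
#' the genes the herb most activates sit at the bottom of the disease
#' ranking and vice versa, so the herb reverses the disease pattern by
#' construction and its Total Matching Score is negative (strongly so at
#' `noise_sd = 0`).
#'
#' @param final_sig Named numeric final signature of the planted herb.
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   fold changes (default 0).
#' @param seed Integer seed.
#' @param t Extreme-set size the profile must support; the signature must
#'   carry at least `2t` distinct values (default 25).
#' @param id Profile identifier.
#' @return A [ranked_profile()] over the signature's genes.
#' @export
make_planted_reversal_profile <- function(final_sig, noise_sd = 0, seed = 1L,
                                          t = 25, id = "planted_reversal") {
  if (length(unique(final_sig)) < 2L * t) {
    stop("degenerate signature: fewer than ", 2L * t, " distinct values")
  }
  withr::with_seed(seed, {
    fc <- -as.numeric(final_sig) +
      stats::rnorm(length(final_sig), mean = 0, sd = noise_sd)
    ranked_profile(names(final_sig), fc, id = id)
  })
}

#' Fixture with a planted synergistic herb pair
#'
#' Builds a disease profile from the negated sum of two herbs' final
#' signatures (plus noise), so that the pair jointly reverses the disease
#' ranking more strongly than either herb alone. Used as ground truth for
#' combination-search recovery tests.
#'
#' @param network A `ppi_network`.
#' @param library Herb library data frame containing both herbs.
#' @param herb_pair Character vector of two herb ids.
#' @param noise_sd Gaussian noise SD on the fold changes (default 0).
#' @param seed Integer seed.
#' @param t Extreme-set size for downstream scoring (default 25).
#' @param contra Optional [contraindication_set()]; an error is raised if
#'   the planted pair is contraindicated.
#' @return List of class `fixture_bundle`: `network`, `library`,
#'   `herb_finals` (genes x herbs matrix), `profiles` (named list with the
#'   planted profile), `truth` (planted ids and expected TMS sign), `seed`.
#' @export
make_planted_synergy_fixture <- function(network, library, herb_pair,
                                         noise_sd = 0, seed = 1L, t = 25,
                                         contra = NULL) {
  stopifnot(length(herb_pair) == 2L)
  if (!all(herb_pair %in% library$herb_id)) {
    stop("planted herb(s) not in the library: ",
         paste(setdiff(herb_pair, library$herb_id), collapse = ", "))
  }
  if (!is.null(contra) && is_contraindicated(contra, herb_pair[1L],
                                             herb_pair[2L])) {
    stop("planted pair is contraindicated: ",
         paste(herb_pair, collapse = " / "))
  }
  finals <- herb_final_signatures(library, network)
  combined <- finals[, herb_pair[1L]] + finals[, herb_pair[2L]]
  names(combined) <- rownames(finals)
  profile <- withr::with_seed(seed, {
    fc <- -combined + stats::rnorm(length(combined), sd = noise_sd)
    ranked_profile(names(combined), fc, id = "planted_synergy")
  })
  structure(
    list(network = network, library = library, herb_finals = finals,
         profiles = list(planted_synergy = profile),
         truth = list(planted = sort(herb_pair), expected_tms_sign = -1L,
                      t = t),
         seed = seed),
    class = "fixture_bundle"
  )
}

#' Complete synthetic fixture bundle
#'
#' One call producing a network, a herb library, a reversal profile planted
#' on one herb and a synergy profile planted on a herb pair, with the truth
#' record needed by end-to-end tests. Default dimensions are desk scale:
#' a 300-node network, 30 herbs and extreme sets of t = 25.
#'
#' @param seed Integer seed driving every generator.
#' @param n_nodes,n_herbs Network and library sizes.
#' @param t Extreme-set size recorded in the truth.
#' @param noise_sd Gaussian noise SD for both planted profiles.
#' @return A `fixture_bundle` with profiles `planted_reversal` and
#'   `planted_synergy`.
#' @export
make_fixture_bundle <- function(seed = 1L, n_nodes = 300, n_herbs = 30,
                                t = 25, noise_sd = 0) {
  network <- make_network(n_nodes, seed = seed)
  library <- make_herb_library(network, n_herbs = n_herbs, seed = seed + 1L)
  herbs <- unique(library$herb_id)
  planted <- withr::with_seed(seed + 2L, sample(herbs, 3L))
  finals <- herb_final_signatures(library, network)
  reversal <- make_planted_reversal_profile(
    finals[, planted[1L]], noise_sd = noise_sd, seed = seed + 3L, t = t,
    id = "planted_reversal"
  )
  synergy <- make_planted_synergy_fixture(
    network, library, planted[2:3], noise_sd = noise_sd, seed = seed + 4L,
    t = t
  )
  structure(
    list(network = network, library = library, herb_finals = finals,
         profiles = list(planted_reversal = reversal,
                         planted_synergy = synergy$profiles$planted_synergy),
         truth = list(reversal_herb = planted[1L],
                      synergy_pair = sort(planted[2:3]),
                      expected_tms_sign = -1L, t = t),
         seed = seed),
    class = "fixture_bundle"
  )
}

#' Write a fixture bundle to a directory
#'
#' Lays out `network.tsv`, `herbs.tsv`, one `profiles/<id>.rnk` per profile
#' and a `truth.json` record.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  net <- bundle$network
  idx <- Matrix::which(Matrix::triu(net$adj) != 0, arr.ind = TRUE)
  write_network_edges(cbind(net$nodes[idx[, 1L]], net$nodes[idx[, 2L]]),
                      file.path(dir, "network.tsv"))
  write_herb_library(bundle$library, file.path(dir, "herbs.tsv"))
  for (id in names(bundle$profiles)) {
    write_ranked_profile(bundle$profiles[[id]],
                         file.path(dir, "profiles", paste0(id, ".rnk")))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(c(bundle$truth, list(seed = bundle$seed)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
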