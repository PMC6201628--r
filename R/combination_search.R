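# Genetic-algorithm search over herb subsets: fitness-proportional
# selection, uniform crossover, bit-flip mutation, elitism, and continuous
# repair against contraindication pairs and a combination-size cap.
#
# Solutions are fixed-length logical inclusion vectors over the herb
# library. Because diffusion is linear, the final signature of a
# combination equals the sum of its member herbs' final signatures, so the
# per-herb final signatures are computed once and combinations are scored
# by summing columns.

#' Genetic-algorithm configuration
#'
#' @param pop_size Population size (default 500).
#' @param t Extreme-set size used in the fitness (default 250; a solution's
#'   signature spans `2t` genes).
#' @param max_combo_size Maximum number of herbs per solution (default 8).
#' @param crossover_prob Probability a parent pair is recombined (default 0.9).
#' @param mutation_rate Per-herb bit-flip probability; `NULL` means `1/L`
#'   for a library of `L` herbs.
#' @param elitism_count Number of best solutions copied unchanged into the
#'   next generation (default 1).
#' @param max_generations Hard generation cap (default 200).
#' @param stall_generations Terminate after this many generations without
#'   improvement of the best fitness (default 20).
#' @param objective `"abs_tms"` (maximise |TMS|, the default) or
#'   `"negative_tms"` (maximise -TMS, i.e. seek the strongest reversal of
#'   the disease ranking).
#' @param seed Integer seed; all randomness of the run flows from it.
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 500, t = 250, max_combo_size = 8,
                      crossover_prob = 0.9, mutation_rate = NULL,
                      elitism_count = 1, max_generations = 200,
                      stall_generations = 20,
                      objective = c("abs_tms", "negative_tms"),
                      seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(pop_size >= 2, t >= 1, max_combo_size >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            elitism_count >= 0, elitism_count < pop_size,
            max_generations >= 1, stall_generations >= 1)
  structure(
    list(pop_size = as.integer(pop_size), t = as.integer(t),
         max_combo_size = as.integer(max_combo_size),
         crossover_prob = crossover_prob, mutation_rate = mutation_rate,
         elitism_count = as.integer(elitism_count),
         max_generations = as.integer(max_generations),
         stall_generations = as.integer(stall_generations),
         objective = objective, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Fitness-proportional (roulette) parent selection
#'
#' Samples `count` parents with replacement with probability
#' `P_i = f_i / sum(f)`. If every fitness is zero the fallback is uniform.
#'
#' @param fitnesses Non-negative numeric vector.
#' @param count Number of parents to draw.
#' @return Integer vector of selected indices.
#' @export
select_parents <- function(fitnesses, count) {
  if (length(fitnesses) == 0L) stop("empty population")
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  tot <- sum(fitnesses)
  prob <- if (tot > 0) fitnesses / tot else rep(1 / length(fitnesses),
                                                length(fitnesses))
  sample.int(length(fitnesses), count, replace = TRUE, prob = prob)
}

#' Uniform crossover of two inclusion vectors
#'
#' With probability `prob`, each herb's inclusion bit in each child is drawn
#' from one of the two parents with probability 1/2 (the second child takes
#' the complementary choice); otherwise the children are copies of the
#' parents.
#'
#' @param a,b Logical inclusion vectors of equal length.
#' @param prob Crossover probability.
#' @return List of two logical vectors.
#' @export
crossover_solutions <- function(a, b, prob = 0.9) {
  stopifnot(length(a) == length(b))
  if (stats::runif(1) >= prob) return(list(a, b))
  take_a <- stats::runif(length(a)) < 0.5
  list(ifelse(take_a, a, b), ifelse(take_a, b, a))
}

#' Bit-flip mutation of an inclusion vector
#' @param sol Logical inclusion vector.
#' @param rate Per-bit flip probability.
#' @return Mutated logical vector.
#' @export
mutate_solution <- function(sol, rate) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- stats::runif(length(sol)) < rate
  xor(sol, flip)
}

#' Repair a candidate solution to validity
#'
#' An empty candidate gains one random herb. While a contraindicated pair
#' remains, the member with the lower cached singleton fitness is removed
#' (ties at random). While the size cap is exceeded, a random member is
#' removed. Always terminates: every step strictly shrinks a violation.
#'
#' @param sol Logical inclusion vector over the herb library.
#' @param herb_ids Character vector of herb ids (library order).
#' @param contra A [contraindication_set()] or `NULL`.
#' @param max_combo_size Size cap.
#' @param herb_fitness Optional per-herb singleton fitness used to pick
#'   which member of a contraindicated pair to drop; uniform-random when
#'   omitted.
#' @return A valid logical inclusion vector.
#' @export
repair_solution <- function(sol, herb_ids, contra = NULL, max_combo_size = 8,
                            herb_fitness = NULL) {
  L <- length(sol)
  if (!any(sol)) sol[sample.int(L, 1L)] <- TRUE
  if (!is.null(contra) && length(contra$keys) > 0L) {
    repeat {
      members <- herb_ids[sol]
      if (length(members) < 2L) break
      cmb <- utils::combn(members, 2L)
      bad <- which(is_contraindicated(contra, cmb[1L, ], cmb[2L, ]))
      if (length(bad) == 0L) break
      pair <- cmb[, bad[1L]]
      drop <- if (is.null(herb_fitness)) {
        pair[sample.int(2L, 1L)]
      } else {
        fa <- herb_fitness[[pair[1L]]]
        fb <- herb_fitness[[pair[2L]]]
        if (fa < fb) pair[1L] else if (fb < fa) pair[2L]
        else pair[sample.int(2L, 1L)]
      }
      sol[match(drop, herb_ids)] <- FALSE
      if (!any(sol)) sol[sample.int(L, 1L)] <- TRUE
    }
  }
  while (sum(sol) > max_combo_size) {
    sol[sample(which(sol), 1L)] <- FALSE
  }
  sol
}

#' Initialise a random population of herb combinations
#'
#' Each solution draws its size uniformly in `[1, max_combo_size]`, then
#' samples that many herbs without replacement; contraindicated draws are
#' repaired. Reproducible from the config seed (call inside
#' `withr::with_seed()` or rely on [search_herb_combination()]).
#'
#' @param herb_ids Character vector of library herb ids.
#' @param config A [ga_config()].
#' @param contra A [contraindication_set()] or `NULL`.
#' @return Logical matrix, `pop_size` x `L`, one solution per row.
#' @export
init_population <- function(herb_ids, config, contra = NULL) {
  L <- length(herb_ids)
  if (L < 1L) stop("empty herb library")
  max_size <- min(config$max_combo_size, L)
  pop <- matrix(FALSE, nrow = config$pop_size, ncol = L,
                dimnames = list(NULL, herb_ids))
  for (i in seq_len(config$pop_size)) {
    size <- sample.int(max_size, 1L)
    sol <- logical(L)
    sol[sample.int(L, size)] <- TRUE
    pop[i, ] <- repair_solution(sol, herb_ids, contra, max_size)
  }
  pop
}

# Fitness of one inclusion vector given the precomputed herb final-signature
# matrix. Memoised in `cache` (an environment) keyed by the member set.
.solution_score <- function(sol, herb_finals, profile, t, objective, cache) {
  key <- paste(which(sol), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  final <- if (sum(sol) == 1L) herb_finals[, which(sol)] else
    rowSums(herb_finals[, sol, drop = FALSE])
  names(final) <- rownames(herb_finals)
  res <- tryCatch({
    sig <- extreme_signature(final, t = t, id = key)
    total_matching_score(profile, sig)$tms
  }, error = function(e) NA_real_)
  fitness <- if (is.na(res)) NA_real_ else
    switch(objective, abs_tms = abs(res), negative_tms = max(0, -res))
  out <- list(tms = res, fitness = fitness)
  cache[[key]] <- out
  out
}

#' Genetic-algorithm search for the optimal herb combination
#'
#' Searches herb subsets for the combination whose extreme signature best
#' matches (under `objective = "abs_tms"`, most strongly matches or
#' reverses; under `"negative_tms"`, most strongly reverses) the disease
#' profile. Each generation: evaluate all solutions with the
#' combination-level Total Matching Score, copy the `elitism_count` best
#' unchanged, fill the rest by roulette selection, uniform crossover,
#' bit-flip mutation and repair. Terminates at `max_generations` or after
#' `stall_generations` without improvement (beyond 1e-12) of the best
#' fitness. The whole run is reproducible from `config$seed`.
#'
#' @param herb_finals Numeric matrix of per-herb final signatures
#'   (genes x herbs), e.g. from [herb_final_signatures()].
#' @param profile A [ranked_profile()].
#' @param config A [ga_config()].
#' @param contra A [contraindication_set()] or `NULL`.
#' @return List of class `combo_search_result` with `best_herbs` (character
#'   vector), `best_fitness`, `best_tms`, `trace` (data frame with columns
#'   `generation`, `best_fitness`, `mean_fitness`), `generations`,
#'   `config`.
#' @export
search_herb_combination <- function(herb_finals, profile, config,
                                    contra = NULL) {
  stopifnot(is.matrix(herb_finals), inherits(config, "ga_config"))
  herb_ids <- colnames(herb_finals)
  if (is.null(herb_ids)) stop("herb_finals must have column names (herb ids)")
  withr::with_seed(config$seed, {
    .run_ga(herb_finals, profile, config, contra, herb_ids)
  })
}

.run_ga <- function(herb_finals, profile, config, contra, herb_ids) {
  L <- length(herb_ids)
  rate <- if (is.null(config$mutation_rate)) 1 / L else config$mutation_rate
  cache <- new.env(parent = emptyenv())

  # singleton fitnesses, used by repair to drop the weaker herb of a pair
  herb_fitness <- vapply(herb_ids, function(h) {
    sol <- herb_ids == h
    f <- .solution_score(sol, herb_finals, profile, config$t,
                         config$objective, cache)$fitness
    if (is.na(f)) 0 else f
  }, numeric(1))

  evaluate_all <- function(pop) {
    fit <- numeric(nrow(pop))
    tms <- numeric(nrow(pop))
    for (i in seq_len(nrow(pop))) {
      s <- .solution_score(pop[i, ], herb_finals, profile, config$t,
                           config$objective, cache)
      # a degenerate solution (unscorable) is resampled
      attempts <- 0L
      while (is.na(s$fitness) && attempts < 50L) {
        sol <- logical(L)
        sol[sample.int(L, sample.int(min(config$max_combo_size, L), 1L))] <- TRUE
        pop[i, ] <- repair_solution(sol, herb_ids, contra,
                                    config$max_combo_size, herb_fitness)
        s <- .solution_score(pop[i, ], herb_finals, profile, config$t,
                             config$objective, cache)
        attempts <- attempts + 1L
      }
      if (is.na(s$fitness)) stop("could not draw a scorable solution")
      fit[i] <- s$fitness
      tms[i] <- s$tms
    }
    list(pop = pop, fitness = fit, tms = tms)
  }

  pop <- init_population(herb_ids, config, contra)
  trace <- data.frame(generation = integer(0), best_fitness = numeric(0),
                      mean_fitness = numeric(0))
  best_fit <- -Inf
  best_sol <- NULL
  best_tms <- NA_real_
  stall <- 0L
  gen <- 0L

  repeat {
    gen <- gen + 1L
    ev <- evaluate_all(pop)
    pop <- ev$pop
    top <- which.max(ev$fitness)
    if (ev$fitness[top] > best_fit + 1e-12) {
      best_fit <- ev$fitness[top]
      best_sol <- pop[top, ]
      best_tms <- ev$tms[top]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- rbind(trace, data.frame(generation = gen,
                                     best_fitness = best_fit,
                                     mean_fitness = mean(ev$fitness)))
    if (gen >= config$max_generations || stall >= config$stall_generations) {
      break
    }

    # next generation: elites + offspring
    elite_idx <- order(-ev$fitness)[seq_len(config$elitism_count)]
    nxt <- pop[elite_idx, , drop = FALSE]
    while (nrow(nxt) < config$pop_size) {
      par <- select_parents(ev$fitness, 2L)
      kids <- crossover_solutions(pop[par[1L], ], pop[par[2L], ],
                                  config$crossover_prob)
      for (kid in kids) {
        if (nrow(nxt) >= config$pop_size) break
        kid <- mutate_solution(kid, rate)
        kid <- repair_solution(kid, herb_ids, contra, config$max_combo_size,
                               herb_fitness)
        nxt <- rbind(nxt, matrix(kid, nrow = 1L))
      }
    }
    colnames(nxt) <- herb_ids
    pop <- nxt
  }

  structure(
    list(best_herbs = herb_ids[best_sol], best_fitness = best_fit,
         best_tms = best_tms, trace = trace, generations = gen,
         config = config),
    class = "combo_search_result"
  )
}

#' @export
print.combo_search_result <- function(x, ...) {
  cat("Best combination:", paste(x$best_herbs, collapse = " + "), "\n")
  cat(sprintf("fitness = %.4f (TMS = %.4f) after %d generation(s)\n",
              x$best_fitness, x$best_tms, x$generations))
  invisible(x)
}

#' Exhaustive search over all herb combinations up to a size cap
#'
#' Brute-force reference for small libraries: enumerates every subset of
#' size 1..`max_size` that respects the contraindications and returns the
#' best under the same objective as the genetic algorithm.
#'
#' @inheritParams search_herb_combination
#' @param max_size Maximum subset size to enumerate.
#' @param t Extreme-set size.
#' @param objective `"abs_tms"` or `"negative_tms"`.
#' @return List with `best_herbs`, `best_fitness`, `best_tms`, `n_evaluated`.
#' @export
enumerate_combinations <- function(herb_finals, profile, max_size = 2,
                                   t = 25, objective = c("abs_tms",
                                                         "negative_tms"),
                                   contra = NULL) {
  objective <- match.arg(objective)
  herb_ids <- colnames(herb_finals)
  L <- length(herb_ids)
  cache <- new.env(parent = emptyenv())
  best <- list(best_herbs = character(0), best_fitness = -Inf,
               best_tms = NA_real_, n_evaluated = 0L)
  for (size in seq_len(min(max_size, L))) {
    sets <- utils::combn(L, size)
    for (k in seq_len(ncol(sets))) {
      members <- herb_ids[sets[, k]]
      if (.violates_contra(members, contra)) next
      sol <- herb_ids %in% members
      s <- .solution_score(sol, herb_finals, profile, t, objective, cache)
      best$n_evaluated <- best$n_evaluated + 1L
      if (!is.na(s$fitness) && s$fitness > best$best_fitness) {
        best$best_herbs <- members
        best$best_fitness <- s$fitness
        best$best_tms <- s$tms
      }
    }
  }
  best
}
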