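# Shared small fixture: 8-herb library on a 150-node network with a planted
# synergistic pair, scored with t = 15.
combo_fixture <- function(seed = 101) {
  net <- make_network(150, seed = seed)
  lib <- make_herb_library(net, n_herbs = 8, seed = seed + 1)
  make_planted_synergy_fixture(net, lib, c("herb_003", "herb_006"),
                               seed = seed + 2, t = 15)
}

test_that("roulette selection follows fitness-proportional probabilities", {
  withr::with_seed(1, {
    draws <- select_parents(c(3, 1), 10000)
    p_hat <- mean(draws == 1)
    se <- sqrt(0.75 * 0.25 / 10000)
    expect_lt(abs(p_hat - 0.75), 3 * se)

    unif <- select_parents(c(2, 2, 2, 2), 8000)
    expect_lt(max(abs(tabulate(unif, 4) / 8000 - 0.25)), 0.02)

    zero <- select_parents(c(0, 0, 0), 3000)
    expect_lt(max(abs(tabulate(zero, 3) / 3000 - 1 / 3)), 0.03)
  })
  expect_error(select_parents(numeric(0), 1), "empty")
  expect_error(select_parents(c(-1, 1), 1), "non-negative")
})

test_that("uniform crossover respects probability and parent union", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, TRUE, FALSE)
  withr::with_seed(2, {
    kids <- crossover_solutions(a, b, prob = 0)
    expect_identical(kids[[1]], a)
    expect_identical(kids[[2]], b)

    same <- crossover_solutions(a, a, prob = 1)
    expect_identical(same[[1]], a)
    expect_identical(same[[2]], a)

    for (rep in 1:20) {
      kids <- crossover_solutions(a, b, prob = 1)
      for (kid in kids) {
        expect_true(all(which(kid) %in% which(a | b)))
        # complementary children partition the parents' bits
      }
      expect_identical(kids[[1]] | kids[[2]], a | b)
      expect_identical(kids[[1]] & kids[[2]], a & b)
    }
  })
})

test_that("mutation flips bits at the given rate", {
  sol <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  withr::with_seed(3, {
    expect_identical(mutate_solution(sol, 0), sol)
    expect_identical(mutate_solution(sol, 1), !sol)
    a <- withr::with_seed(9, mutate_solution(sol, 0.5))
    b <- withr::with_seed(9, mutate_solution(sol, 0.5))
    expect_identical(a, b)
  })
})

test_that("repair produces valid solutions in all degenerate cases", {
  ids <- paste0("h", 1:5)
  contra <- contraindication_set(rbind(c("h1", "h2")))
  withr::with_seed(4, {
    fixed <- repair_solution(rep(FALSE, 5), ids)
    expect_equal(sum(fixed), 1)

    both <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    rep1 <- repair_solution(both, ids, contra)
    expect_equal(sum(rep1), 1)

    valid <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
    expect_identical(repair_solution(valid, ids, contra), valid)

    capped <- repair_solution(rep(TRUE, 5), ids, NULL, max_combo_size = 2)
    expect_equal(sum(capped), 2)

    # fitness-guided drop removes the weaker member of the pair
    guided <- repair_solution(both, ids, contra,
                              herb_fitness = c(h1 = 0.9, h2 = 0.1, h3 = 0,
                                               h4 = 0, h5 = 0))
    expect_identical(which(guided), 1L)
  })
})

test_that("initial populations are valid, sized and seed-reproducible", {
  ids <- paste0("h", 1:10)
  cfg <- ga_config(pop_size = 20, t = 5, max_combo_size = 3, seed = 8)
  contra <- contraindication_set(rbind(c("h1", "h2")))
  pop <- withr::with_seed(8, init_population(ids, cfg, contra))
  expect_equal(dim(pop), c(20, 10))
  sizes <- rowSums(pop)
  expect_true(all(sizes >= 1 & sizes <= 3))
  expect_false(any(pop[, 1] & pop[, 2]))
  pop2 <- withr::with_seed(8, init_population(ids, cfg, contra))
  expect_identical(pop, pop2)
})

test_that("ga_config validates its fields", {
  expect_s3_class(ga_config(), "ga_config")
  expect_equal(ga_config()$pop_size, 500L)
  expect_equal(ga_config()$t, 250L)
  expect_error(ga_config(crossover_prob = 1.5))
  expect_error(ga_config(pop_size = 1))
  expect_error(ga_config(objective = "maximal"))
})

test_that("search reduces to single-herb scoring on a one-herb library", {
  fx <- combo_fixture()
  one <- fx$herb_finals[, "herb_003", drop = FALSE]
  profile <- fx$profiles$planted_synergy
  cfg <- ga_config(pop_size = 5, t = 15, max_combo_size = 2,
                   max_generations = 3, stall_generations = 2, seed = 31)
  res <- search_herb_combination(one, profile, cfg)
  expect_equal(res$best_herbs, "herb_003")

  v <- one[, 1]
  names(v) <- rownames(one)
  sig <- extreme_signature(v, t = 15, id = "herb_003")
  expect_equal(res$best_fitness,
               abs(total_matching_score(profile, sig)$tms))
})

test_that("best fitness is non-decreasing and constraints always hold", {
  fx <- combo_fixture()
  contra <- contraindication_set(rbind(c("herb_001", "herb_002")))
  for (seed in c(5, 6, 7)) {
    cfg <- ga_config(pop_size = 30, t = 15, max_combo_size = 3,
                     max_generations = 15, stall_generations = 5, seed = seed)
    res <- search_herb_combination(fx$herb_finals,
                                   fx$profiles$planted_synergy, cfg, contra)
    expect_true(all(diff(res$trace$best_fitness) >= 0))
    expect_lte(length(res$best_herbs), 3)
    expect_false(all(c("herb_001", "herb_002") %in% res$best_herbs))
    expect_equal(nrow(res$trace), res$generations)
  }
})

test_that("a one-generation budget runs exactly one generation", {
  fx <- combo_fixture()
  cfg <- ga_config(pop_size = 10, t = 15, max_combo_size = 2,
                   max_generations = 1, stall_generations = 5, seed = 2)
  res <- search_herb_combination(fx$herb_finals, fx$profiles$planted_synergy,
                                 cfg)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$generations, 1)
})

test_that("runs are bitwise reproducible from the config seed", {
  fx <- combo_fixture()
  cfg <- ga_config(pop_size = 20, t = 15, max_combo_size = 2,
                   max_generations = 10, stall_generations = 4, seed = 55)
  r1 <- search_herb_combination(fx$herb_finals, fx$profiles$planted_synergy, cfg)
  r2 <- search_herb_combination(fx$herb_finals, fx$profiles$planted_synergy, cfg)
  expect_identical(r1$best_herbs, r2$best_herbs)
  expect_identical(r1$trace, r2$trace)
})

test_that("the GA reaches the exhaustive optimum on small libraries", {
  fx <- combo_fixture()
  exact <- enumerate_combinations(fx$herb_finals,
                                  fx$profiles$planted_synergy,
                                  max_size = 2, t = 15)
  expect_setequal(exact$best_herbs, fx$truth$planted)

  hits <- 0
  for (seed in 1:10) {
    cfg <- ga_config(pop_size = 30, t = 15, max_combo_size = 2,
                     max_generations = 25, stall_generations = 8, seed = seed)
    res <- search_herb_combination(fx$herb_finals,
                                   fx$profiles$planted_synergy, cfg)
    if (abs(res$best_fitness - exact$best_fitness) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("exhaustive enumeration respects contraindications", {
  fx <- combo_fixture()
  contra <- contraindication_set(rbind(fx$truth$planted))
  constrained <- enumerate_combinations(fx$herb_finals,
                                        fx$profiles$planted_synergy,
                                        max_size = 2, t = 15, contra = contra)
  expect_false(setequal(constrained$best_herbs, fx$truth$planted))
})
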