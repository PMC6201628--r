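triangle <- function() {
  build_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

test_that("ingredient signatures carry signed modes and reject conflicts", {
  v <- ingredient_signature(c("A", "B"), c(1, -1))
  expect_equal(unname(v[c("A", "B")]), c(1, -1))

  dup <- ingredient_signature(c("A", "A"), c(1, 1))
  expect_equal(as.numeric(dup), 1)

  expect_error(ingredient_signature(c("A", "A"), c(1, -1), id = "ing1"),
               "conflicting modes for gene A.*ing1")
  expect_error(ingredient_signature("A", 2), "\\+1 or -1")
})

test_that("herb signatures superpose ingredients with content weights", {
  i1 <- ingredient_signature("A", 1)
  i2 <- ingredient_signature(c("A", "B"), c(1, -1))
  v <- herb_signature(list(i1, i2))
  expect_equal(unname(v[c("A", "B")]), c(2, -1))

  w <- herb_signature(list(ingredient_signature("A", 1),
                           ingredient_signature("B", -1)),
                      contents = c(0.2, 0.8))
  expect_equal(unname(w[c("A", "B")]), c(0.2, -0.8))

  single <- herb_signature(list(i2))
  expect_equal(as.numeric(single[names(i2)]), as.numeric(i2))

  expect_error(herb_signature(list()), "no ingredients")
  expect_message(herb_signature(list(i1, i2), contents = c(0.5, NA)),
                 "mixes known and unknown")
  expect_error(herb_signature(list(i1), contents = 1.5), "\\(0, 1\\]")
})

test_that("combination signatures are commutative, weighted sums", {
  h1 <- c(A = 2)
  h2 <- c(A = -2, B = 1)
  v <- combination_signature(list(h1, h2))
  expect_equal(v[["A"]], 0)
  expect_equal(v[["B"]], 1)

  disj <- combination_signature(list(c(A = 1), c(B = -1)))
  expect_equal(sort(names(disj)), c("A", "B"))

  ab <- combination_signature(list(h1, h2))
  ba <- combination_signature(list(h2, h1))
  expect_equal(ab[sort(names(ab))], ba[sort(names(ba))])

  expect_error(combination_signature(list()), "no herbs")
})

test_that("final signatures diffuse initial values and drop outside targets", {
  tri <- triangle()
  out <- final_signature(tri, c(A = 1))
  expect_equal(unname(out[c("A", "B", "C")]), c(0.5, 0.25, 0.25))

  expect_message(out2 <- final_signature(tri, c(A = 1, ZZZ = 1)), "outside")
  expect_equal(unname(out2), unname(out))

  expect_error(suppressMessages(final_signature(tri, c(ZZZ = 1))),
               "no targets remain")
})

test_that("diffusion is additive across herbs (linearity end-to-end)", {
  tri <- triangle()
  h1 <- c(A = 1, B = -1)
  h2 <- c(C = 2)
  combo <- combination_signature(list(h1, h2))
  expect_equal(unname(final_signature(tri, combo)),
               unname(final_signature(tri, h1) + final_signature(tri, h2)),
               tolerance = 1e-12)
})

test_that("extreme signatures take the t largest and smallest genes", {
  v <- stats::setNames(c(5, 4, 3, 2, 1, 0), paste0("g", 1:6))
  sig <- extreme_signature(v, t = 2, id = "x")
  expect_equal(sort(sig$top), c("g1", "g2"))
  expect_equal(sort(sig$bottom), c("g5", "g6"))

  expect_error(extreme_signature(stats::setNames(rnorm(300),
                                                 sprintf("g%03d", 1:300)),
                                 t = 250),
               "need at least 500")

  flat <- stats::setNames(rep(1, 4), c("d", "c", "b", "a"))
  s1 <- extreme_signature(flat, t = 1)
  expect_equal(s1$top, "a")    # lexicographic head of the tie plateau
  expect_equal(s1$bottom, "d") # tail of the same ordering: disjoint
})

test_that("extreme sets are always disjoint with |top| = |bottom| = t", {
  withr::with_seed(5, {
    for (rep in 1:40) {
      n <- sample(10:80, 1)
      t <- sample(1:(n %/% 2), 1)
      # random values with heavy ties to stress the tie rule
      v <- stats::setNames(sample(round(rnorm(n), 1)), sprintf("g%03d", 1:n))
      sig <- extreme_signature(v, t = t)
      expect_length(sig$top, t)
      expect_length(sig$bottom, t)
      expect_length(intersect(sig$top, sig$bottom), 0)
    }
  })
})

test_that("jaccard distance matches set arithmetic and is a metric", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a", "b"), c("c", "d")), 1)
  expect_equal(jaccard_distance(c("a", "b"), c("b", "c")), 2 / 3)
  expect_error(jaccard_distance(character(0), character(0)), "empty")

  withr::with_seed(21, {
    universe <- letters
    for (rep in 1:50) {
      a <- sample(universe, sample(1:10, 1))
      b <- sample(universe, sample(1:10, 1))
      c <- sample(universe, sample(1:10, 1))
      expect_equal(jaccard_distance(a, b), jaccard_distance(b, a))
      expect_lte(jaccard_distance(a, c),
                 jaccard_distance(a, b) + jaccard_distance(b, c) + 1e-12)
    }
  })
})

test_that("probe collapse keeps the minimum-p probe per gene", {
  stats_tbl <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    gene = c("G", "G", "H"),
    p_value = c(0.01, 0.5, 0.2),
    fold_change = c(2.0, -1.0, 0.5)
  )
  out <- collapse_probes(stats_tbl)
  expect_equal(out$fold_change[out$gene == "G"], 2.0)
  expect_equal(nrow(out), 2)

  tie <- data.frame(
    probe_id = c("pa", "pb"), gene = "G",
    p_value = 0.01, fold_change = c(1.0, -3.0)
  )
  expect_equal(collapse_probes(tie)$fold_change, -3.0)

  single <- data.frame(probe_id = "p1", gene = "G", p_value = 0.1,
                       fold_change = 1.2)
  expect_equal(collapse_probes(single)$fold_change, 1.2)

  expect_error(collapse_probes(data.frame(probe_id = c("p", "p"), gene = "G",
                                          p_value = 0.1, fold_change = 1)),
               "duplicate probe")
})

test_that("disease profiles rank by descending fold change", {
  p <- build_disease_profile(data.frame(gene = c("g1", "g2", "g3"),
                                        fold_change = c(2, -1, 0.5)))
  expect_equal(p$gene, c("g1", "g3", "g2"))
  expect_equal(nrow(build_disease_profile(
    data.frame(gene = "g", fold_change = 1))), 1)
  tied <- build_disease_profile(data.frame(gene = c("b", "a"),
                                           fold_change = c(1, 1)))
  expect_equal(tied$gene, c("a", "b"))
})

test_that("library-wide signatures superpose per herb with content rules", {
  lib <- data.frame(
    herb_id = c("h1", "h1", "h1", "h2"),
    ingredient_id = c("i1", "i1", "i2", "i3"),
    target_gene = c("A", "B", "A", "C"),
    mode = c(1, -1, -1, 1),
    content = NA_real_
  )
  sigs <- herb_initial_signatures(lib)
  # cross-ingredient conflict on A sums to 0 (allowed), within-ingredient not
  expect_equal(sigs$h1[["A"]], 0)
  expect_equal(sigs$h1[["B"]], -1)
  expect_equal(as.numeric(sigs$h2), 1)

  tri <- triangle()
  lib2 <- data.frame(
    herb_id = "h1", ingredient_id = "i1", target_gene = "A",
    mode = 1, content = NA_real_
  )
  m <- herb_final_signatures(lib2, tri)
  expect_equal(unname(m[, "h1"]), c(0.5, 0.25, 0.25))
})
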