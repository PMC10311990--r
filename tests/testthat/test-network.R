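test_that("feedforward weights have exact counts and sign pattern", {
  w <- build_feedforward_weights(200, 100, 80, seed = 1)
  expect_identical(sum(w > 0), 80L)
  expect_identical(sum(w < 0), 20L)
  expect_identical(sum(w == 0), 100L)
  expect_true(all(w >= -8 & w <= 8))

  expect_equal(build_feedforward_weights(50, 0, 0, seed = 2), rep(0, 50))
  expect_identical(build_feedforward_weights(200, seed = 3),
                   build_feedforward_weights(200, seed = 3))
  expect_error(build_feedforward_weights(10, 20, 5), "n_connected")
  expect_error(build_feedforward_weights(10, 5, 6), "n_excitatory")
})

test_that("recurrent circuits have exact in-degree and E:I split", {
  g <- build_recurrent_circuit(300, in_degree = 120, seed = 1)
  deg <- table(g$edges$post)
  expect_length(deg, 300)
  expect_true(all(deg == 120))  # point mass at in_degree
  expect_true(all(g$edges$pre != g$edges$post))
  # per-neuron 4:1 excitatory:inhibitory count split (96 vs 24)
  pos <- tapply(g$edges$weight > 0, g$edges$post, sum)
  expect_true(all(pos == 96))
  # no duplicate directed edges
  expect_false(anyDuplicated(g$edges[, c("pre", "post")]) > 0)
})

test_that("reciprocity matches the target mixture and edge kinds", {
  g <- build_recurrent_circuit(600, in_degree = 120, p_uni = 0.13,
                               p_rec = 0.06, seed = 2)
  key <- paste(pmin(g$edges$pre, g$edges$post),
               pmax(g$edges$pre, g$edges$post))
  tab <- table(key)
  frac <- mean(tab == 2)
  expect_lt(abs(frac - 0.06 / 0.19), 0.01)
  # mutual pairs are exactly the reciprocal-kind edges
  mutual <- names(tab)[tab == 2]
  expect_setequal(unique(key[g$edges$kind == "reciprocal"]), mutual)

  # p_rec = 0 yields no reciprocal pair at feasible density
  g0 <- build_recurrent_circuit(80, in_degree = 10, p_rec = 0, seed = 3)
  key0 <- paste(pmin(g0$edges$pre, g0$edges$post),
                pmax(g0$edges$pre, g0$edges$post))
  expect_true(all(table(key0) == 1))
  expect_true(all(g0$edges$kind == "unidirectional"))

  # infeasible: in-degree 120 on 200 nodes cannot avoid mutual pairs
  expect_error(build_recurrent_circuit(200, 120, p_rec = 0, seed = 4,
                                       max_tries = 2), "infeasible")

  # saturated in-structure: every in-neighborhood is all other neurons
  gs <- build_recurrent_circuit(31, in_degree = 30, seed = 5)
  expect_true(all(table(gs$edges$post) == 30))
  expect_true(all(table(paste(pmin(gs$edges$pre, gs$edges$post),
                              pmax(gs$edges$pre, gs$edges$post))) == 2))
})

test_that("reciprocal members are 1.5x stronger before clipping", {
  g <- build_recurrent_circuit(400, in_degree = 60, clip = FALSE, seed = 6)
  mag <- abs(g$edges$weight)
  rec <- g$edges$kind == "reciprocal"
  expect_gt(max(mag[rec]), 8)  # scaling can exceed the base range
  expect_true(all(mag[!rec] <= 8))
  ratio <- mean(mag[rec]) / mean(mag[!rec])
  expect_gt(ratio, 1.35)
  expect_lt(ratio, 1.65)
  # with clipping the range is restored
  gc <- build_recurrent_circuit(100, in_degree = 20, clip = TRUE, seed = 7)
  expect_true(all(abs(gc$edges$weight) <= 8))
})

test_that("circuit rates are moment-matched lognormal draws", {
  g <- build_recurrent_circuit(2000, in_degree = 20, seed = 8)
  r <- assign_circuit_rates(g, 0.8703, 0.8749, seed = 9)
  expect_length(r, 2000)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - 0.8703), 4 * 0.8749 / sqrt(2000))

  # the population-level lognormal rate law uses the same moment matching
  spec <- population_spec(1e5, rate_law = "lognormal",
                          lognormal_mean = 3.7, lognormal_sd = 3.5)
  rr <- generate_raster(spec, 1, 1, seed = 10)$meta$rates
  expect_lt(abs(mean(rr) - 3.7), 4 * 3.5 / sqrt(1e5))
  expect_lt(abs(sd(rr) - 3.5), 4 * 3.5 / sqrt(1e5) * 3)
  expect_error(assign_circuit_rates(g, -1, 1), "moments")
})

test_that("circuit edge lists round-trip through delimited text", {
  g <- build_recurrent_circuit(40, in_degree = 8, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_circuit(g, path)
  g2 <- read_circuit(path)
  expect_equal(g2$edges$weight, g$edges$weight)
  expect_identical(g2$edges$pre, g$edges$pre)
  expect_identical(g2$edges$kind, g$edges$kind)
  expect_identical(g2$n_neurons, 40L)
})
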