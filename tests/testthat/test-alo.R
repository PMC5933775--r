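test_that("great-value-priority binarization follows the rank rule", {
  expect_equal(gvp_binarize(c(3, 2, 1)), c(0, 0, 0))
  expect_equal(gvp_binarize(c(1, 2, 3)), c(1, 1, 0))
  expect_equal(gvp_binarize(5), 0L)
  expect_equal(gvp_binarize(c(0.5, 0.5)), c(0, 0))  # ties: lower index first
  expect_error(gvp_binarize(numeric()), "non-empty")
  set.seed(1)
  for (i in 1:20) {
    y <- gvp_binarize(runif(sample(1:8, 1)))
    expect_true(all(y %in% 0:1))
    expect_equal(y[length(y)], 0L)
  }
})

test_that("roulette selection is fitness-proportionate after shifting", {
  expect_equal(roulette_select(42), 1L)
  set.seed(10)
  draws <- roulette_select(c(1, 1, 1, 1), n = 10000)
  expect_gt(chisq.test(table(factor(draws, levels = 1:4)))$p.value, 0.001)
  # negative fitness: shifted weights are (50, ~0), so index 2 is rare
  draws <- roulette_select(c(5, -45), n = 10000)
  p1 <- mean(draws == 1)
  expect_gt(p1, 1 - 3 * sqrt(0.5 / 10000) - 0.01)
})

test_that("flip mutation changes exactly one dimension", {
  expect_equal(flip_mutation(c(0, 1, 0), i = 2), c(0, 0, 0))
  set.seed(20)
  for (i in 1:20) {
    x <- rbinom(6, 1, 0.5)
    y <- flip_mutation(x)
    expect_equal(sum(x != y), 1)
    expect_true(all(y %in% 0:1))
  }
  expect_equal(flip_mutation(flip_mutation(c(1, 0), i = 1), i = 1), c(1, 0))
})

test_that("ant crossover mixes the two guides bit by bit", {
  RA <- c(0, 0, 0, 0); RE <- c(1, 1, 1, 1)
  expect_equal(ant_update(RA, RA, r = runif(4)), RA)
  expect_equal(ant_update(RA, RE, r = rep(0.1, 4)), RE)
  expect_equal(ant_update(RA, RE, r = rep(0.9, 4)), RA)
  mix <- ant_update(RA, RE, r = c(0.1, 0.9, 0.1, 0.9))
  expect_equal(mix, c(1, 0, 1, 0))
  expect_error(ant_update(c(0, 1), c(1, 0, 0)), "equal length")
})

test_that("catch-and-rebuild replaces only on strict improvement", {
  M <- make_worked_instance()
  set.seed(30)
  st <- initialize_population(M, alo_params(4, 4, 10), lambda = 50)
  st$ants[1, ] <- c(0, 1, 0, 1); st$ant_fitness[1] <- 5
  st$antlions[2, ] <- c(1, 0, 0, 0); st$antlion_fitness[2] <- 1
  up <- catch_and_rebuild(st, 1, 2)
  expect_equal(up$antlions[2, ], c(0, 1, 0, 1))
  expect_equal(up$antlion_fitness[2], 5)
  st$ant_fitness[1] <- 1   # ties leave the ant lion unchanged
  expect_identical(catch_and_rebuild(st, 1, 2)$antlions[2, ],
                   st$antlions[2, ])
  st$ant_fitness[1] <- -44
  expect_identical(catch_and_rebuild(st, 1, 2)$antlion_fitness[2], 1)
})

test_that("initialization seeds binary colonies and a consistent elite", {
  M <- make_worked_instance()
  set.seed(40); st1 <- initialize_population(M, alo_params(20, 15, 5), 50)
  set.seed(40); st2 <- initialize_population(M, alo_params(20, 15, 5), 50)
  expect_identical(st1, st2)
  expect_equal(dim(st1$ants), c(20, 4))
  expect_equal(dim(st1$antlions), c(15, 4))
  expect_true(all(st1$ants %in% 0:1) && all(st1$antlions %in% 0:1))
  expect_equal(st1$elite_fitness, max(st1$antlion_fitness))
})

test_that("the optimizer finds the worked instance optimum from any seed", {
  M <- make_worked_instance()
  for (s in 1:10) {
    sol <- alo_solve(M, alo_params(30, 30, 40), lambda = 50, seed = s)
    expect_equal(sol$fitness$fitness, 5)
    expect_true(sol$feasible)
  }
})

test_that("elite traces are monotone and runs are seed-deterministic", {
  for (gs in 71:90) {
    pool <- generate_kpd_pool(30, seed = gs)
    M <- enumerate_exchanges(build_compat_matrix(pool), 3)
    if (length(M) >= 5) break
  }
  a <- alo_solve(M, alo_params(40, 40, 60), seed = 5)
  b <- alo_solve(M, alo_params(40, 40, 60), seed = 5)
  expect_identical(a$selection, b$selection)
  expect_identical(a$trace, b$trace)
  expect_true(all(diff(a$trace) >= 0))
  expect_true(all(a$selection %in% 0:1))
  # the reported breakdown can only improve on the graded search score
  expect_gte(a$fitness$fitness, max(a$trace))
  # longer runs never do worse under the same seed
  short <- alo_solve(M, alo_params(40, 40, 1), seed = 9)
  long <- alo_solve(M, alo_params(40, 40, 60), seed = 9)
  expect_gte(long$fitness$fitness, short$fitness$fitness)
})

test_that("heuristic plus repair reaches the exact optimum on small pools", {
  wins <- 0; total <- 0
  for (s in 1:20) {
    pool <- random_pool(sample(6:9, 1), 1, 0.35, seed = 800 + s)
    M <- enumerate_exchanges(build_compat_matrix(pool), 3)
    if (length(M) == 0 || length(M) > 10) next
    best <- solve_exact(M)$utility
    sol <- kpd_solve(M, "alo", alo_params(50, 50, 60), seed = s)
    total <- total + 1
    if (sol$utility == best) wins <- wins + 1
  }
  expect_gte(wins / total, 0.95)
})
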