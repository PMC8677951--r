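# hand-set toy landscape over a 2-group space for argmax verification
toy_evaluator <- function(values) {
  function(a) {
    key <- paste(a$choices, collapse = "_")
    c(on = values[[key]], off = 0)
  }
}

test_that("random initial assignments are reproducible and cover the library uniformly", {
  lib <- substituent_library()
  a1 <- random_initial_assignment("A2B2C2", lib, seed = 42)
  a2 <- random_initial_assignment("A2B2C2", lib, seed = 42)
  expect_identical(a1$choices, a2$choices)

  lib1 <- lib[4, , drop = FALSE]
  expect_equal(random_initial_assignment("A3B3", lib1, seed = 1)$choices,
               c("H", "H"))

  # chi-square uniformity over 1e4 draws, per group
  n <- 10000
  draws <- t(vapply(seq_len(n), function(s)
    random_initial_assignment("A3B3", lib, seed = s)$choices, character(2)))
  for (g in 1:2) {
    counts <- table(factor(draws[, g], levels = lib$label))
    chi <- sum((counts - n / 7)^2 / (n / 7))
    expect_lt(chi, qchisq(1 - 1e-4, df = 6))  # ~4-sigma bound
  }
})

test_that("exhaustive search finds the verified argmax on a toy space", {
  lib2 <- substituent_library()[c(4, 7), ]   # H, NH2
  vals <- list(H_H = 1, H_NH2 = 5, NH2_H = 3, NH2_NH2 = 2)
  cfg <- bfs_config(objective = "difference")
  ex <- exhaustive_search("A3B3", lib2, toy_evaluator(vals), cfg)
  expect_equal(ex$best_assignment$choices, c("H", "NH2"))
  expect_equal(ex$best_objective, 5)
  expect_equal(sort(ex$values), c(1, 2, 3, 5))
  expect_error(exhaustive_search("A2BC2D", substituent_library(),
                                 toy_evaluator(vals), cfg, guard = 100),
               "guard")
})

test_that("BFS equals exhaustive search on additive (independent-site) landscapes", {
  lib <- substituent_library()
  for (seed in 1:6) {
    spec <- synthetic_landscape("A2B2C2", lib, seed = seed, coupling_sd = 0,
                                symmetry_cancellation = FALSE)
    ev <- synthetic_evaluator(spec)
    cfg <- bfs_config(seed = seed * 13 + 1, objective = "difference")
    res <- run_bfs("A2B2C2", lib, ev, cfg)
    ex <- exhaustive_search("A2B2C2", lib, ev, cfg)
    expect_equal(res$best_objective, ex$best_objective)
    expect_equal(res$best_assignment$choices, ex$best_assignment$choices)
    # additive optimum = composition of per-group argmaxes
    per_group <- lib$label[apply(spec$base[["26R"]] - spec$base[["28R"]],
                                 1, which.max)]
    expect_equal(ex$best_assignment$choices, per_group)
  }
})

test_that("a constant landscape converges after one sweep to the initial assignment", {
  lib <- substituent_library()
  ev <- function(a) c(on = 1000, off = 100)
  res <- run_bfs("A2B2C2", lib, ev, bfs_config(seed = 9, objective = "difference"))
  expect_true(res$converged)
  expect_equal(res$sweeps, 1L)
  init <- random_initial_assignment("A2B2C2", lib, seed = 9)
  expect_equal(res$best_assignment$choices, init$choices)
})

test_that("with couplings BFS is bounded by the exhaustive optimum and monotone", {
  lib <- substituent_library()
  spec <- synthetic_landscape("A2B2C2", lib, seed = 7, coupling_sd = 800,
                              symmetry_cancellation = TRUE)
  ev <- synthetic_evaluator(spec)
  cfg <- bfs_config(seed = 7, objective = "difference")
  res <- run_bfs("A2B2C2", lib, ev, cfg)
  ex <- exhaustive_search("A2B2C2", lib, ev, cfg)
  expect_gte(res$best_objective, res$initial_objective)
  expect_lte(res$best_objective, ex$best_objective)
  acc <- res$trajectory$objective[res$trajectory$accepted]
  expect_true(all(diff(acc) >= 0))
  # the greedy search touches only a fraction of the 343-point space
  expect_lt(res$evaluations, space_size("A2B2C2", lib))
  expect_lte(res$evaluations,
             res$sweeps * 3 * nrow(lib) + 1)
})

test_that("the evaluation cache prevents re-evaluating any structure", {
  lib <- substituent_library()
  seen <- new.env(parent = emptyenv())
  counting <- function(a) {
    key <- paste(a$choices, collapse = "_")
    if (exists(key, envir = seen)) stop("structure evaluated twice: ", key)
    assign(key, TRUE, envir = seen)
    c(on = sum(match(a$choices, lib$label)) * 100, off = 0)
  }
  res <- run_bfs("A2B2C2", lib, counting,
                 bfs_config(seed = 3, objective = "difference"))
  expect_equal(res$evaluations, length(ls(seen)))
  expect_gt(res$cache_hits, 0)
})

test_that("the persisted cache lets a rerun resume without new evaluations", {
  lib <- substituent_library()
  cache <- withr::local_tempfile(fileext = ".jsonl")
  spec <- synthetic_landscape("A3B3", lib, seed = 2, coupling_sd = 0,
                              symmetry_cancellation = FALSE)
  ev <- synthetic_evaluator(spec)
  cfg <- bfs_config(seed = 4, objective = "difference", cache_file = cache)
  res1 <- run_bfs("A3B3", lib, ev, cfg)
  expect_gt(res1$evaluations, 0)
  res2 <- run_bfs("A3B3", lib, ev, cfg)
  expect_equal(res2$evaluations, 0L)      # everything served from the cache
  expect_equal(res2$best_objective, res1$best_objective)
})

test_that("evaluator failures follow the configured policy", {
  lib <- substituent_library()
  flaky <- function(a) {
    if ("NO2" %in% a$choices) stop("backend failure")
    c(on = sum(nchar(a$choices)) * 10, off = 0)
  }
  expect_error(run_bfs("A3B3", lib, flaky,
                       bfs_config(seed = 1, objective = "difference")),
               "evaluator failed")
  res <- run_bfs("A3B3", lib, flaky,
                 bfs_config(seed = 1, objective = "difference",
                            on_error = "minus_inf"))
  expect_false("NO2" %in% res$best_assignment$choices)
  expect_true(is.finite(res$best_objective))
})
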