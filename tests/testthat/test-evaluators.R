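test_that("packaged reference tables load, validate and serve lookups", {
  fx <- load_fixtures()
  expect_s3_class(fx, "paper_fixtures")
  lookup <- table_evaluator(fx)
  # unsubstituted parents, static and dynamic
  expect_equal(lookup("26R(H)"), 2347)
  expect_equal(lookup("28M(H)", frequency = 1.165), 5679)
  expect_equal(lookup("28R(H)"), 0)
  # pairwise disubstitution series and the centrosymmetric OFF entries
  expect_equal(lookup("26R(NH2_H_H)"), 1.56e4)
  expect_equal(lookup("28R(F)"), 0)
  expect_equal(lookup("28R(NO2_H_H)"), 1340)  # C2 exception to the formal rule
  # misses carry the offending key
  expect_error(lookup("26R(XYZ)"), "26R\\(XYZ\\)")
  expect_error(lookup("26R(F)", frequency = 1.165), "1.165")
  expect_error(lookup("26R(F)", frequency = 0.5), "frequency")
})

test_that("malformed or inconsistent fixture files abort with row diagnostics", {
  dir <- withr::local_tempdir()
  rec <- utils::read.csv(system.file("extdata", "hexaphyrin_records.csv",
                                     package = "hexanlo"))
  bad <- rec
  bad$beta_hrs_static[2] <- -5
  p <- file.path(dir, "bad.csv")
  utils::write.csv(bad, p, row.names = FALSE)
  expect_error(load_fixtures(records_path = p), "row 2")

  # a zero beta without the Ci tag violates the storage convention
  bad2 <- rec
  i <- which(bad2$key == "28R(F)")
  bad2$symmetry[i] <- "C1"
  p2 <- file.path(dir, "bad2.csv")
  utils::write.csv(bad2, p2, row.names = FALSE)
  expect_error(load_fixtures(records_path = p2), "Ci")

  # a corrupted beta breaks the transcribed-contrast recomputation
  bad3 <- rec
  bad3$beta_hrs_static[bad3$key == "26R(CN)"] <- 9999
  p3 <- file.path(dir, "bad3.csv")
  utils::write.csv(bad3, p3, row.names = FALSE)
  expect_error(load_fixtures(records_path = p3), "recomputed")

  expect_error(load_fixtures(records_path = file.path(dir, "nothere.csv")),
               "not found")
  # schema mismatch: missing required column
  p4 <- file.path(dir, "cols.csv")
  utils::write.csv(rec[, setdiff(names(rec), "symmetry")], p4,
                   row.names = FALSE)
  expect_error(load_fixtures(records_path = p4), "symmetry")
})

test_that("every transcribed contrast cell is reproduced from its ON/OFF betas", {
  fx <- load_fixtures()
  lookup <- table_evaluator(fx)
  con <- fx$contrasts
  for (r in seq_len(nrow(con))) {
    pair <- switch_pair(lookup(sprintf("%s(%s)", con$on_state[r],
                                       con$substituent[r])),
                        lookup(sprintf("%s(%s)", con$off_state[r],
                                       con$substituent[r])),
                        on_label = con$on_state[r])
    expect_equal(ratio_contrast(pair)$ratio, con$ratio[r],
                 tolerance = 0.01)
    d <- difference_contrast(pair)
    expect_lt(abs(d - con$difference[r]),
              0.01 * max(abs(con$difference[r]),
                         pair$beta_on + pair$beta_off))
  }
})

test_that("fixture-backed switch evaluator feeds BFS on a covered sub-space", {
  fx <- load_fixtures()
  ev <- fixture_switch_evaluator(fx, on_state = "26R")
  a <- assignment("A2B2C2", c("NH2", "OH", "NH2"))
  betas <- ev(a)
  expect_equal(unname(betas), c(35200, 0))
  # structures outside the printed tables are lookup errors (policy-handled)
  expect_error(ev(assignment("A2B2C2", c("OH", "NH2", "OH"))), "no reference")
})

test_that("synthetic landscapes are deterministic and mirror the symmetry physics", {
  lib <- substituent_library()
  s1 <- synthetic_landscape("A2B2C2", lib, seed = 11)
  s2 <- synthetic_landscape("A2B2C2", lib, seed = 11)
  ev1 <- synthetic_evaluator(s1); ev2 <- synthetic_evaluator(s2)
  for (seed in 1:10) {
    a <- random_initial_assignment("A2B2C2", lib, seed = seed)
    expect_identical(ev1(a), ev2(a))
  }
  # cancellation: every A2B2C2 28R structure is formally centrosymmetric,
  # so OFF is exactly 0 unless a symmetry breaker (NO2) is present
  all_h <- assignment("A2B2C2", c("H", "H", "H"))
  expect_equal(ev1(all_h)[["off"]], 0)
  with_no2 <- assignment("A2B2C2", c("NO2", "H", "H"))
  expect_gt(ev1(with_no2)[["off"]], 0)
  # cancelled OFF states push clamped ratio contrasts into the >= 1e5 regime
  for (seed in 1:10) {
    a <- random_initial_assignment("A2B2C2", lib, seed = 100 + seed)
    betas <- ev1(a)
    if (betas[["off"]] == 0 && betas[["on"]] >= 100) {
      res <- evaluate_switch(switch_pair(betas[["on"]], 0), "ratio")
      expect_true(res$clamped)
      expect_gte(res$ratio, 1e5)
    }
  }
  # misconfiguration: fragment outside the landscape library
  phf <- assignment("A2B2C2", c("PhF5", "H", "H"),
                    library = substituent_library(include_phf5 = TRUE))
  expect_error(ev1(phf), "missing from the landscape")
})

test_that("external-evaluator protocol round-trips through request/response files", {
  dir <- withr::local_tempdir()
  fixed <- single_component_tensor(1000)
  responder <- function(req, resp) {
    request <- jsonlite::read_json(req)
    expect_true(all(c("key", "state", "sites", "frequency_eV") %in%
                      names(request)))
    if (request$state == "28R") {
      write_beta_tensor(beta_tensor(array(0, c(3, 3, 3))), resp)
    } else {
      write_beta_tensor(fixed, resp)
    }
  }
  ev <- external_evaluator(dir, responder = responder)
  betas <- ev(assignment("A2B2C2", c("NH2", "OH", "NH2")))
  expect_equal(betas[["on"]], beta_hrs(fixed)$beta_hrs)
  expect_equal(betas[["off"]], 0)

  # malformed response -> evaluator failure that BFS policy can absorb
  bad_responder <- function(req, resp) writeLines("{not json", resp)
  ev_bad <- external_evaluator(file.path(dir, "bad"), responder = bad_responder)
  expect_error(ev_bad(assignment("A2B2C2", c("H", "H", "H"))))

  # no responder and no file -> timeout
  ev_none <- external_evaluator(file.path(dir, "none"), timeout = 0.2)
  expect_error(ev_none(assignment("A2B2C2", c("H", "H", "H"))), "timed out")
})
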