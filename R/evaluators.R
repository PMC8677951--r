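#' Load the packaged hexaphyrin reference tables
#'
#' Reads the hand-transcribed DFT reference data shipped with the package:
#' one row per (structure, state) with geometry descriptors, aromaticity
#' descriptors where available, \eqn{\beta_{HRS}} at up to three photon
#' energies (0, 0.653, 1.165 eV), a symmetry tag and a provenance tag.
#' Entries printed as "approximately zero" in the source tables are stored as
#' exactly 0 a.u. with symmetry `Ci`; the handful of disubstituted `28R`
#' structures that relax to C2 instead of Ci carry their nonzero betas and a
#' `C2` tag.
#'
#' On load every row is validated: finite non-negative betas, 0-beta rows
#' tagged Ci, unique keys, and — for the fully substituted switch series —
#' agreement between the transcribed contrast cells and contrasts recomputed
#' from the stored ON/OFF betas (1% on ratios; differences to 1% of the
#' printed value or of the combined ON+OFF magnitude, whichever is larger,
#' since a difference of two rounded 3-digit values can carry a relative
#' error exceeding the printed precision). A validation failure aborts and
#' lists every violating row.
#'
#' @param records_path,contrasts_path optional overrides for the packaged
#'   CSVs
#' @param validate run the load-time checks (default TRUE)
#' @return list of class `paper_fixtures` with data.frames `records` and
#'   `contrasts`.
#' @export
load_fixtures <- function(records_path = NULL, contrasts_path = NULL,
                          validate = TRUE) {
  if (is.null(records_path)) {
    records_path <- system.file("extdata", "hexaphyrin_records.csv",
                                package = "hexanlo", mustWork = TRUE)
  }
  if (is.null(contrasts_path)) {
    contrasts_path <- system.file("extdata", "table2_contrasts.csv",
                                  package = "hexanlo", mustWork = TRUE)
  }
  if (!file.exists(records_path)) {
    stop(sprintf("fixture file not found: %s", records_path), call. = FALSE)
  }
  rec <- utils::read.csv(records_path, stringsAsFactors = FALSE)
  con <- utils::read.csv(contrasts_path, stringsAsFactors = FALSE)

  needed <- c("key", "state", "pattern", "choices", "beta_hrs_static",
              "symmetry", "provenance")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop(sprintf("fixture schema mismatch: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  if (validate) {
    problems <- character()
    beta_cols <- intersect(c("beta_hrs_static", "beta_hrs_0653",
                             "beta_hrs_1165"), names(rec))
    for (r in seq_len(nrow(rec))) {
      betas <- unlist(rec[r, beta_cols])
      bad <- !is.na(betas) & (betas < 0 | !is.finite(betas))
      if (any(bad)) {
        problems <- c(problems, sprintf("row %d (%s): negative or non-finite beta",
                                        r, rec$key[r]))
      }
      if (!is.na(rec$beta_hrs_static[r]) && rec$beta_hrs_static[r] == 0 &&
          rec$symmetry[r] != "Ci") {
        problems <- c(problems, sprintf(
          "row %d (%s): zero beta must carry symmetry tag Ci", r, rec$key[r]))
      }
    }
    if (anyDuplicated(rec$key)) {
      problems <- c(problems, sprintf("duplicate key(s): %s",
        paste(unique(rec$key[duplicated(rec$key)]), collapse = ", ")))
    }
    # recompute the fully substituted switch-series contrast cells
    for (r in seq_len(nrow(con))) {
      on_key <- sprintf("%s(%s)", con$on_state[r], con$substituent[r])
      off_key <- sprintf("%s(%s)", con$off_state[r], con$substituent[r])
      bon <- rec$beta_hrs_static[rec$key == on_key]
      boff <- rec$beta_hrs_static[rec$key == off_key]
      if (length(bon) != 1L || length(boff) != 1L ||
          is.na(bon) || is.na(boff)) {
        problems <- c(problems, sprintf(
          "contrast row %d: missing record %s or %s", r, on_key, off_key))
        next
      }
      if (bon < 0 || boff < 0) next   # already reported above

      pair <- switch_pair(bon, boff, on_label = con$on_state[r],
                          off_label = con$off_state[r])
      ratio <- ratio_contrast(pair)$ratio
      diff <- difference_contrast(pair)
      if (abs(ratio - con$ratio[r]) > 0.01 * abs(con$ratio[r])) {
        problems <- c(problems, sprintf(
          "contrast row %d (%s/%s): recomputed ratio %.4g vs printed %.4g",
          r, con$substituent[r], con$on_state[r], ratio, con$ratio[r]))
      }
      dtol <- 0.01 * max(abs(con$difference[r]), bon + boff)
      if (abs(diff - con$difference[r]) > dtol) {
        problems <- c(problems, sprintf(
          "contrast row %d (%s/%s): recomputed difference %.4g vs printed %.4g",
          r, con$substituent[r], con$on_state[r], diff, con$difference[r]))
      }
    }
    if (length(problems) > 0) {
      stop(paste(c("fixture validation failed:", problems), collapse = "\n  "),
           call. = FALSE)
    }
  }
  structure(list(records = rec, contrasts = con), class = "paper_fixtures")
}

#' @export
print.paper_fixtures <- function(x, ...) {
  cat(sprintf("<paper_fixtures> %d records, %d transcribed contrast cells\n",
              nrow(x$records), nrow(x$contrasts)))
  invisible(x)
}

.freq_column <- function(frequency) {
  col <- c(`0` = "beta_hrs_static", `0.653` = "beta_hrs_0653",
           `1.165` = "beta_hrs_1165")[as.character(frequency)]
  if (is.na(col)) {
    stop(sprintf("no reference betas at frequency %g eV (have 0, 0.653, 1.165)",
                 frequency), call. = FALSE)
  }
  col
}

#' Reference-table property evaluator
#'
#' Replays the transcribed DFT \eqn{\beta_{HRS}} values so the search engine
#' is testable without quantum chemistry. Pure lookup by canonical structure
#' key and frequency; no interpolation. A key absent from the tables (or a
#' key whose beta is unprinted at the requested frequency) raises a lookup
#' error carrying the key, which the search's error policy then handles —
#' the tables cover only the structures the source prints, not whole search
#' spaces.
#'
#' @param fixtures a [load_fixtures()] result
#' @return function(key, frequency = 0) returning \eqn{\beta_{HRS}} in a.u.
#' @export
table_evaluator <- function(fixtures) {
  stopifnot(inherits(fixtures, "paper_fixtures"))
  rec <- fixtures$records
  function(key, frequency = 0) {
    col <- .freq_column(frequency)
    i <- which(rec$key == key)
    if (length(i) == 0L) {
      stop(sprintf("no reference record for key '%s'", key), call. = FALSE)
    }
    v <- rec[[col]][i[1]]
    if (is.na(v)) {
      stop(sprintf("no beta printed for key '%s' at %g eV", key, frequency),
           call. = FALSE)
    }
    v
  }
}

#' Switch evaluator backed by the reference tables
#'
#' Adapter for [run_bfs()]: evaluates both states of the switch for an
#' assignment by key lookup.
#'
#' @param fixtures a [load_fixtures()] result
#' @param on_state,off_state state labels (`"26R"`/`"28M"` vs `"28R"`)
#' @param frequency photon energy (eV)
#' @return function(assignment) returning `c(on = , off = )`.
#' @export
fixture_switch_evaluator <- function(fixtures, on_state = "26R",
                                     off_state = "28R", frequency = 0) {
  lookup <- table_evaluator(fixtures)
  function(a) {
    c(on = lookup(structure_key(on_state, a), frequency),
      off = lookup(structure_key(off_state, a), frequency))
  }
}

#' Seeded synthetic switch landscape
#'
#' A deterministic stand-in (labelled synthetic throughout) for the DFT
#' property surface, shaped like the hexaphyrin structure-property data: each
#' (group, fragment) carries a log-normal base contribution per state — ON
#' states around a few thousand a.u. with a multiplicative spread, OFF
#' states an order of magnitude smaller — plus optional pairwise inter-site
#' couplings that break the independent-site approximation. When
#' `symmetry_cancellation` is on, a formally centrosymmetric `28R` OFF state
#' scores exactly 0 a.u. (the inversion-center rule) unless a
#' symmetry-breaker fragment (default NO2, which relaxes such structures to
#' C2) appears anywhere in the assignment. Absolute values keep every
#' synthetic beta non-negative.
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @param seed integer seed; same spec + seed give an identical landscape
#'   everywhere
#' @param on_state,off_state state labels
#' @param base_scale_on,base_scale_off median base contribution per group
#'   (a.u.)
#' @param base_log_sd log-normal spread of the base contributions
#' @param coupling_sd standard deviation of the pairwise couplings (a.u.);
#'   0 gives a purely additive (independent-site) landscape
#' @param symmetry_cancellation apply the centrosymmetry -> zero-beta rule
#' @param symmetry_breakers fragment labels exempting a structure from the
#'   cancellation
#' @return list of class `synthetic_landscape`.
#' @export
synthetic_landscape <- function(pattern, library = substituent_library(),
                                seed = 1L, on_state = "26R",
                                off_state = "28R",
                                base_scale_on = 2500, base_scale_off = 300,
                                base_log_sd = 0.8, coupling_sd = 500,
                                symmetry_cancellation = TRUE,
                                symmetry_breakers = "NO2") {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  G <- length(pattern$groups)
  L <- nrow(library)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  base <- list()
  coup <- list()
  for (st in c(on_state, off_state)) {
    scale <- if (st == on_state) base_scale_on else base_scale_off
    base[[st]] <- matrix(scale * exp(stats::rnorm(G * L, 0, base_log_sd)),
                         G, L, dimnames = list(NULL, library$label))
    cp <- array(0, c(G, L, G, L))
    if (coupling_sd > 0 && G > 1) {
      for (g in seq_len(G - 1)) for (h in (g + 1):G) {
        cp[g, , h, ] <- stats::rnorm(L * L, 0, coupling_sd)
      }
    }
    coup[[st]] <- cp
  }
  structure(list(pattern = pattern, library = library, seed = seed,
                 on_state = on_state, off_state = off_state,
                 base = base, coupling = coup,
                 symmetry_cancellation = symmetry_cancellation,
                 symmetry_breakers = symmetry_breakers),
            class = "synthetic_landscape")
}

#' Evaluator over a synthetic landscape
#'
#' @param spec a [synthetic_landscape()]
#' @return function(assignment) returning `c(on = , off = )` in a.u.
#' @export
synthetic_evaluator <- function(spec) {
  stopifnot(inherits(spec, "synthetic_landscape"))
  lib_labels <- spec$library$label
  G <- length(spec$pattern$groups)
  state_value <- function(st, idx) {
    v <- sum(spec$base[[st]][cbind(seq_len(G), idx)])
    cp <- spec$coupling[[st]]
    if (G > 1) {
      for (g in seq_len(G - 1)) for (h in (g + 1):G) {
        v <- v + cp[g, idx[g], h, idx[h]]
      }
    }
    abs(v)
  }
  function(a) {
    if (!identical(a$pattern$name, spec$pattern$name)) {
      stop("assignment pattern does not match landscape pattern",
           call. = FALSE)
    }
    idx <- match(a$choices, lib_labels)
    if (anyNA(idx)) {
      stop(sprintf("fragment '%s' missing from the landscape library",
                   a$choices[which(is.na(idx))[1]]), call. = FALSE)
    }
    on <- state_value(spec$on_state, idx)
    off <- state_value(spec$off_state, idx)
    if (spec$symmetry_cancellation && spec$off_state == "28R" &&
        is_formally_centrosymmetric("28R", expand_assignment(a)) &&
        !any(a$choices %in% spec$symmetry_breakers)) {
      off <- 0
    }
    c(on = on, off = off)
  }
}

#' File-based external-evaluator protocol
#'
#' Contract seam toward a quantum-chemistry backend. For each state of the
#' switch the evaluator writes a structure request JSON into `job_dir`
#' (canonical key, state, per-site substituent map, frequency) and expects a
#' responder to deposit a `hexanlo-beta-v1` tensor file alongside it; the
#' tensor is then reduced with [beta_hrs()]. `responder` is called as
#' `responder(request_path, response_path)` after each request is written —
#' in production it would dispatch to a compute cluster, in tests it is a
#' stub. Without a responder the evaluator polls for the response file until
#' `timeout` seconds have passed; a missing or malformed response is an
#' evaluator failure (the search's error policy applies).
#'
#' @param job_dir writable directory for request/response files
#' @param on_state,off_state state labels
#' @param frequency photon energy (eV)
#' @param responder optional function(request_path, response_path)
#' @param timeout seconds to wait for a response file
#' @return function(assignment) returning `c(on = , off = )`.
#' @export
external_evaluator <- function(job_dir, on_state = "26R", off_state = "28R",
                               frequency = 0, responder = NULL, timeout = 5) {
  if (!dir.exists(job_dir)) dir.create(job_dir, recursive = TRUE)
  fetch_beta <- function(state, a) {
    key <- structure_key(state, a)
    slug <- gsub("[^A-Za-z0-9_]", "-", key)
    req <- file.path(job_dir, sprintf("request-%s.json", slug))
    resp <- file.path(job_dir, sprintf("response-%s.json", slug))
    jsonlite::write_json(list(key = key, state = state,
                              sites = as.list(expand_assignment(a)),
                              frequency_eV = frequency),
                         req, auto_unbox = TRUE, digits = NA)
    if (!is.null(responder)) {
      responder(req, resp)
    } else {
      t0 <- Sys.time()
      while (!file.exists(resp) &&
             as.numeric(Sys.time() - t0, units = "secs") < timeout) {
        Sys.sleep(0.05)
      }
    }
    if (!file.exists(resp)) {
      stop(sprintf("external evaluator timed out waiting for %s", resp),
           call. = FALSE)
    }
    beta_hrs(read_beta_tensor(resp))$beta_hrs
  }
  function(a) {
    c(on = fetch_beta(on_state, a), off = fetch_beta(off_state, a))
  }
}
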