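#' Configuration for a best-first-search run
#'
#' @param seed integer seed for the random initial structure
#' @param max_global_sweeps cap on full passes over the sites (>= 1); the
#'   search stops earlier when a complete sweep yields no improvement
#' @param objective `"ratio"` or `"difference"` contrast objective
#' @param clamp_threshold,clamp_value OFF-state clamp parameters (see
#'   [ratio_contrast()])
#' @param site_order permutation of group indices to visit per sweep
#'   (default ascending); `NULL` means `1:n_groups`
#' @param on_error what to do when the evaluator fails on a structure:
#'   `"abort"` rethrows, `"minus_inf"` scores the candidate `-Inf` and logs
#' @param on_label,off_label state labels of the switch being optimized
#' @param frequency photon-energy tag (eV) passed to cache keys
#' @param cache_file optional JSONL path: evaluations are appended as they
#'   happen and reloaded on restart, so interrupted runs resume
#' @return list of class `bfs_config`.
#' @export
bfs_config <- function(seed = 1L, max_global_sweeps = 10L,
                       objective = c("ratio", "difference"),
                       clamp_threshold = 10, clamp_value = 0.001,
                       site_order = NULL,
                       on_error = c("abort", "minus_inf"),
                       on_label = "26R", off_label = "28R",
                       frequency = 0, cache_file = NULL) {
  stopifnot(max_global_sweeps >= 1)
  structure(list(seed = as.integer(seed),
                 max_global_sweeps = as.integer(max_global_sweeps),
                 objective = match.arg(objective),
                 clamp_threshold = clamp_threshold,
                 clamp_value = clamp_value,
                 site_order = site_order,
                 on_error = match.arg(on_error),
                 on_label = on_label, off_label = off_label,
                 frequency = frequency,
                 cache_file = cache_file),
            class = "bfs_config")
}

#' Random initial assignment
#'
#' Draws one substituent per group, independently and uniformly from the
#' library; reproducible for a fixed seed (caller's RNG state untouched).
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @param seed integer seed
#' @return an [assignment()].
#' @export
random_initial_assignment <- function(pattern, library = substituent_library(),
                                      seed = 1L) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(nrow(library), length(pattern$groups), replace = TRUE)
  assignment(pattern, library$label[idx], library)
}

# objective value of a (beta_on, beta_off) pair under a bfs_config
.objective_value <- function(betas, config) {
  pair <- switch_pair(betas[["on"]], betas[["off"]],
                      on_label = config$on_label,
                      off_label = config$off_label,
                      frequency = config$frequency)
  res <- evaluate_switch(pair, objective = config$objective,
                         clamp_threshold = config$clamp_threshold,
                         clamp_value = config$clamp_value)
  res$objective_value
}

.cache_key <- function(a, config) {
  sprintf("%s|%s|%g", a$pattern$name, paste(a$choices, collapse = "_"),
          config$frequency)
}

.load_cache <- function(path) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(line)) next
      rec <- jsonlite::fromJSON(line)
      assign(rec$key, c(on = rec$on, off = rec$off), envir = cache)
    }
  }
  cache
}

#' Best-first-search inverse design
#'
#' Greedy site-by-site maximization of a switch-contrast objective over a
#' substitution chemical compound space. Starting from a random assignment,
#' the search visits the pattern groups in `site_order`; for each group it
#' evaluates every library fragment with all other groups fixed and accepts
#' the candidate with the strictly largest improvement (ties between equal
#' best candidates fall to the earlier library entry; equal-valued candidates
#' never replace the incumbent, which guarantees termination). Sweeps repeat
#' until a full sweep accepts nothing or `max_global_sweeps` is reached.
#' Every evaluated structure is cached by its canonical key so no structure
#' is evaluated twice.
#'
#' Under the independent-site approximation (an additive property landscape)
#' a single sweep reaches the global optimum; with inter-site couplings the
#' search is a heuristic bounded above by [exhaustive_search()].
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @param evaluator function(assignment) returning
#'   `c(on = beta_on, off = beta_off)` — the \eqn{\beta_{HRS}} of both switch
#'   states (a contrast objective needs both)
#' @param config a [bfs_config()]
#' @return list of class `bfs_result`: `best_assignment`, `best_objective`,
#'   `trajectory` (data.frame: sweep, group, candidate, key, beta_on,
#'   beta_off, objective, accepted, cached), `evaluations`, `cache_hits`,
#'   `converged`, `sweeps`, `initial_objective`.
#' @export
run_bfs <- function(pattern, library, evaluator, config = bfs_config()) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  G <- length(pattern$groups)
  order_ <- if (is.null(config$site_order)) seq_len(G) else config$site_order
  stopifnot(setequal(order_, seq_len(G)))

  cache <- .load_cache(config$cache_file)
  evaluations <- 0L
  cache_hits <- 0L
  traj <- list()

  eval_assignment <- function(a) {
    key <- .cache_key(a, config)
    if (exists(key, envir = cache, inherits = FALSE)) {
      cache_hits <<- cache_hits + 1L
      return(list(betas = get(key, envir = cache), cached = TRUE))
    }
    betas <- tryCatch(evaluator(a), error = function(e) e)
    if (inherits(betas, "error")) {
      if (config$on_error == "abort") {
        stop(sprintf("evaluator failed on %s: %s",
                     paste(a$choices, collapse = "_"),
                     conditionMessage(betas)), call. = FALSE)
      }
      return(list(betas = NULL, cached = FALSE))
    }
    evaluations <<- evaluations + 1L
    assign(key, betas, envir = cache)
    if (!is.null(config$cache_file)) {
      cat(jsonlite::toJSON(list(key = key, on = unname(betas[["on"]]),
                                off = unname(betas[["off"]])),
                           auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = config$cache_file, append = TRUE)
    }
    list(betas = betas, cached = FALSE)
  }

  score <- function(a) {
    ev <- eval_assignment(a)
    if (is.null(ev$betas)) {
      return(list(value = -Inf, betas = c(on = NA_real_, off = NA_real_),
                  cached = ev$cached))
    }
    list(value = .objective_value(ev$betas, config), betas = ev$betas,
         cached = ev$cached)
  }

  current <- random_initial_assignment(pattern, library, config$seed)
  cur <- score(current)
  initial_objective <- cur$value
  traj[[1]] <- data.frame(sweep = 0L, group = NA_integer_,
                          candidate = paste(current$choices, collapse = "_"),
                          key = .cache_key(current, config),
                          beta_on = cur$betas[["on"]],
                          beta_off = cur$betas[["off"]],
                          objective = cur$value, accepted = TRUE,
                          cached = cur$cached, stringsAsFactors = FALSE)

  converged <- FALSE
  sweeps <- 0L
  while (sweeps < config$max_global_sweeps && !converged) {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (g in order_) {
      best_cand <- NULL
      best_val <- cur$value
      for (li in seq_len(nrow(library))) {
        lab <- library$label[li]
        if (lab == current$choices[g]) next
        cand <- current
        cand$choices[g] <- lab
        sc <- score(cand)
        traj[[length(traj) + 1]] <- data.frame(
          sweep = sweeps, group = g, candidate = lab,
          key = .cache_key(cand, config),
          beta_on = sc$betas[["on"]], beta_off = sc$betas[["off"]],
          objective = sc$value, accepted = FALSE, cached = sc$cached,
          stringsAsFactors = FALSE)
        if (sc$value > best_val) {     # strict improvement; first-in-library tie-break
          best_val <- sc$value
          best_cand <- list(a = cand, sc = sc, row = length(traj))
        }
      }
      if (!is.null(best_cand)) {
        current <- best_cand$a
        cur <- best_cand$sc
        traj[[best_cand$row]]$accepted <- TRUE
        improved <- TRUE
      }
    }
    if (!improved) converged <- TRUE
  }

  structure(list(best_assignment = current,
                 best_objective = cur$value,
                 best_betas = cur$betas,
                 trajectory = do.call(rbind, traj),
                 evaluations = evaluations,
                 cache_hits = cache_hits,
                 converged = converged,
                 sweeps = sweeps,
                 initial_objective = initial_objective,
                 config = config),
            class = "bfs_result")
}

#' @export
print.bfs_result <- function(x, ...) {
  cat(sprintf("BFS %s: best %s objective = %.6g after %d sweep(s)%s\n",
              x$best_assignment$pattern$name,
              x$config$objective, x$best_objective, x$sweeps,
              if (x$converged) " (converged)" else " (sweep cap reached)"))
  cat(sprintf("  best structure: %s | evaluations %d, cache hits %d\n",
              paste(x$best_assignment$choices, collapse = "_"),
              x$evaluations, x$cache_hits))
  invisible(x)
}

#' Exhaustive-search oracle
#'
#' Evaluates every assignment in the space and returns the global optimum
#' (ties broken by enumeration order). Guarded against spaces larger than
#' `guard` points.
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @param evaluator function(assignment) returning `c(on=, off=)`
#' @param config a [bfs_config()] (objective and clamp parameters are used)
#' @param guard refuse spaces larger than this (default 1e5)
#' @return list with `best_assignment`, `best_objective`, `values` (objective
#'   of every enumerated assignment, in enumeration order).
#' @export
exhaustive_search <- function(pattern, library, evaluator,
                              config = bfs_config(), guard = 1e5) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  n <- space_size(pattern, library)
  if (n > guard) {
    stop(sprintf("space size %d exceeds exhaustive-search guard %g", n, guard),
         call. = FALSE)
  }
  space <- enumerate_space(pattern, library)
  values <- vapply(space, function(a) {
    .objective_value(evaluator(a), config)
  }, 0)
  best <- which.max(values)            # first max = enumeration-order tie-break
  list(best_assignment = space[[best]], best_objective = values[best],
       values = values)
}
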