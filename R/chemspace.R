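#' Default meso-substituent fragment library
#'
#' The seven-fragment library used in the hexaphyrin inverse-design runs:
#' -NO2, -CN, -F, -H, -CH3, -OH, -NH2, each annotated with its electronic
#' class (electron-withdrawing, electron-donating, neutral) and the dominant
#' character of that effect (mesomeric vs inductive). The pentafluorophenyl
#' group (PhF5) appears only in reference data tables, not in the
#' optimization library; request it with `include_phf5 = TRUE`.
#'
#' @param include_phf5 add the PhF5 fixture-only fragment
#' @return data.frame with columns `label`, `electronic_class`
#'   (`EWG`/`EDG`/`neutral`) and `character` (`mesomeric`/`inductive`/`none`).
#' @export
substituent_library <- function(include_phf5 = FALSE) {
  lib <- data.frame(
    label = c("NO2", "CN", "F", "H", "CH3", "OH", "NH2"),
    electronic_class = c("EWG", "EWG", "EWG", "neutral", "EDG", "EDG", "EDG"),
    character = c("mesomeric", "mesomeric", "inductive", "none",
                  "inductive", "mesomeric", "mesomeric"),
    stringsAsFactors = FALSE
  )
  if (include_phf5) {
    lib <- rbind(lib, data.frame(label = "PhF5", electronic_class = "EWG",
                                 character = "inductive"))
  }
  if (anyDuplicated(lib$label)) stop("duplicate labels in library")
  lib
}

.SITES <- paste0("R", 1:6)

#' Meso-substitution patterns of the hexaphyrin scaffold
#'
#' A pattern partitions the six meso-sites R1..R6 into groups that carry the
#' same substituent:
#' * `FULL` — all six sites identical (fully substituted macrocycles);
#' * `A2B2C2` — diagonally facing pairs (R1,R4), (R2,R5), (R3,R6);
#' * `A3B3` — alternating triples (R1,R3,R5), (R2,R4,R6), the
#'   dipyrromethene + aldehyde condensation route;
#' * `A2BC2D` — (R1,R3), (R2), (R4,R6), (R5), the two-step route admitting up
#'   to four distinct groups.
#'
#' @param name one of `"FULL"`, `"A2B2C2"`, `"A3B3"`, `"A2BC2D"`
#' @return object of class `substitution_pattern`: list with `name` and
#'   `groups`, an ordered list of site-label vectors (disjoint, covering
#'   R1..R6).
#' @export
substitution_pattern <- function(name = c("A2B2C2", "A3B3", "A2BC2D", "FULL")) {
  name <- match.arg(name)
  groups <- switch(name,
    FULL   = list(.SITES),
    A2B2C2 = list(c("R1", "R4"), c("R2", "R5"), c("R3", "R6")),
    A3B3   = list(c("R1", "R3", "R5"), c("R2", "R4", "R6")),
    A2BC2D = list(c("R1", "R3"), "R2", c("R4", "R6"), "R5")
  )
  stopifnot(setequal(unlist(groups), .SITES),
            !anyDuplicated(unlist(groups)))
  structure(list(name = name, groups = groups),
            class = "substitution_pattern")
}

#' @export
print.substitution_pattern <- function(x, ...) {
  cat(sprintf("<substitution_pattern> %s: %s\n", x$name,
              paste(vapply(x$groups, paste, "", collapse = ","),
                    collapse = " | ")))
  invisible(x)
}

#' A point in the substitution chemical compound space
#'
#' An assignment picks one substituent label per pattern group, in group
#' order.
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param choices character vector of substituent labels, one per group
#' @param library fragment library data.frame (validation domain)
#' @return object of class `assignment`.
#' @export
assignment <- function(pattern, choices,
                       library = substituent_library(include_phf5 = TRUE)) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  stopifnot(inherits(pattern, "substitution_pattern"))
  choices <- as.character(choices)
  if (length(choices) != length(pattern$groups)) {
    stop(sprintf("pattern %s needs %d choices, got %d", pattern$name,
                 length(pattern$groups), length(choices)), call. = FALSE)
  }
  bad <- setdiff(choices, library$label)
  if (length(bad) > 0) {
    stop(sprintf("substituent '%s' is not in the library", bad[1]),
         call. = FALSE)
  }
  structure(list(pattern = pattern, choices = choices), class = "assignment")
}

#' Expand an assignment to a per-site substituent map
#'
#' @param a an [assignment()]
#' @return named character vector over sites R1..R6.
#' @examples
#' a <- assignment("A2B2C2", c("NH2", "OH", "NH2"))
#' expand_assignment(a) # R1,R4 = NH2; R2,R5 = OH; R3,R6 = NH2
#' @export
expand_assignment <- function(a) {
  stopifnot(inherits(a, "assignment"))
  map <- setNames(character(6), .SITES)
  for (g in seq_along(a$pattern$groups)) {
    map[a$pattern$groups[[g]]] <- a$choices[g]
  }
  map
}

#' Recover group choices from a per-site map
#'
#' Inverse of [expand_assignment()] for maps that are constant on every
#' pattern group.
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param site_map named character vector over R1..R6
#' @param library fragment library for validation
#' @return an [assignment()].
#' @export
compress_site_map <- function(pattern, site_map,
                              library = substituent_library(include_phf5 = TRUE)) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  choices <- vapply(pattern$groups, function(sites) {
    vals <- unique(unname(site_map[sites]))
    if (length(vals) != 1L) {
      stop(sprintf("site map is not constant on group {%s}",
                   paste(sites, collapse = ",")), call. = FALSE)
    }
    vals
  }, "")
  assignment(pattern, choices, library)
}

#' Canonical structure key
#'
#' `STATE(label_label_...)`, e.g. `26R(NH2_OH_NH2)`; injective over
#' (state, per-site map) within a pattern.
#'
#' @param state one of `"26R"`, `"28R"`, `"28M"`, `"26D"`
#' @param a an [assignment()]
#' @return character scalar key.
#' @export
structure_key <- function(state, a) {
  state <- match.arg(state, c("26R", "28R", "28M", "26D"))
  stopifnot(inherits(a, "assignment"))
  sprintf("%s(%s)", state, paste(a$choices, collapse = "_"))
}

#' A switch structure: macrocycle state plus substitution assignment
#'
#' @param state macrocycle state label (`26R`, `28R`, `28M`, `26D`)
#' @param a an [assignment()]
#' @return object of class `switch_structure` with fields `state`,
#'   `assignment` and the canonical `key`.
#' @export
switch_structure <- function(state, a) {
  state <- match.arg(state, c("26R", "28R", "28M", "26D"))
  structure(list(state = state, assignment = a,
                 key = structure_key(state, a)),
            class = "switch_structure")
}

#' Size of a substitution chemical compound space
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @return `nrow(library) ^ number_of_groups`.
#' @examples
#' space_size("A2B2C2", substituent_library()) # 7^3 = 343
#' @export
space_size <- function(pattern, library = substituent_library()) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  if (nrow(library) == 0) stop("empty library", call. = FALSE)
  nrow(library)^length(pattern$groups)
}

#' Enumerate a substitution space
#'
#' Deterministic lexicographic enumeration by library index: the first group
#' is the most significant digit and the last group cycles fastest, so the
#' first element assigns the first library fragment to every group.
#'
#' @param pattern a [substitution_pattern()] (or its name)
#' @param library fragment library data.frame
#' @return list of [assignment()] objects of length [space_size()].
#' @export
enumerate_space <- function(pattern, library = substituent_library()) {
  if (is.character(pattern)) pattern <- substitution_pattern(pattern)
  G <- length(pattern$groups)
  L <- nrow(library)
  if (L == 0) stop("empty library", call. = FALSE)
  n <- L^G
  out <- vector("list", n)
  for (r in seq_len(n)) {
    rem <- r - 1L
    idx <- integer(G)
    for (g in G:1) {            # last group fastest
      idx[g] <- rem %% L + 1L
      rem <- rem %/% L
    }
    out[[r]] <- assignment(pattern, library$label[idx], library)
  }
  out
}

#' Formal centrosymmetry prediction for a substituted 28R hexaphyrin
#'
#' The unsubstituted `28R` rectangular conformer possesses an inversion
#' center (point group Ci). A substitution preserves that formal symmetry iff
#' the per-site map is invariant under the inversion pairing R1<->R4,
#' R2<->R5, R3<->R6. This is a formal prediction only: reference data may
#' override it when geometry relaxation breaks the symmetry (e.g. the NO2
#' disubstituted 28R relaxes to C2 with a nonzero beta_HRS). Any state other
#' than `28R` is never formally centrosymmetric.
#'
#' @param state macrocycle state label
#' @param site_map named character vector over R1..R6 (see
#'   [expand_assignment()])
#' @return logical.
#' @export
is_formally_centrosymmetric <- function(state, site_map) {
  if (!identical(state, "28R")) return(FALSE)
  all(site_map[c("R1", "R2", "R3")] == site_map[c("R4", "R5", "R6")])
}
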