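#' First-hyperpolarizability tensor
#'
#' Container for a full 3x3x3 first-hyperpolarizability tensor
#' \eqn{\beta_{ijk}} in atomic units, tagged with the photon energy of the
#' incident light (0 eV for the static limit). All hyper-Rayleigh-scattering
#' (HRS) math in the package consumes this object.
#'
#' The second-harmonic-generation (SHG) process \eqn{\beta(-2\omega;
#' \omega, \omega)} is intrinsically symmetric in its last two indices.
#' By default the constructor enforces that symmetry by averaging
#' \eqn{\beta_{ijk}} and \eqn{\beta_{ikj}}; set `symmetrize = FALSE` to keep
#' the components exactly as given (full Kleinman symmetry is never assumed).
#'
#' @param components numeric 3x3x3 array (or length-27 vector filled in array
#'   order) of tensor components in atomic units. Axis order is x, y, z.
#' @param frequency photon energy in eV; 0 means static. Typical dynamic
#'   values for hexaphyrin work are 0.653 eV (1907 nm) and 1.165 eV (1064 nm).
#' @param symmetrize logical; average the last two indices to enforce
#'   intrinsic SHG symmetry.
#'
#' @return An object of class `beta_tensor`: a list with elements
#'   `components` (3x3x3 array, dimnames `x`/`y`/`z`) and `frequency`.
#' @examples
#' b <- array(0, c(3, 3, 3))
#' b[3, 3, 3] <- 1000
#' t <- beta_tensor(b)
#' beta_hrs(t)$beta_hrs # 1000 * sqrt(6/35)
#' @export
beta_tensor <- function(components, frequency = 0, symmetrize = TRUE) {
  if (is.numeric(components) && is.null(dim(components)) &&
      length(components) == 27L) {
    components <- array(components, c(3L, 3L, 3L))
  }
  if (!is.numeric(components) || !identical(dim(components), c(3L, 3L, 3L))) {
    stop("`components` must be a numeric 3x3x3 array", call. = FALSE)
  }
  if (!all(is.finite(components))) {
    stop("all 27 tensor components must be finite", call. = FALSE)
  }
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency < 0) {
    stop("`frequency` must be a single non-negative number (eV)", call. = FALSE)
  }
  comp <- array(as.double(components), c(3L, 3L, 3L),
                dimnames = rep(list(c("x", "y", "z")), 3L))
  obj <- structure(list(components = comp, frequency = as.double(frequency)),
                   class = "beta_tensor")
  if (symmetrize) obj <- symmetrize_shg(obj) else obj
}

#' Enforce intrinsic SHG symmetry on a tensor
#'
#' Replaces \eqn{\beta_{ijk}} by \eqn{(\beta_{ijk} + \beta_{ikj})/2}, the
#' intrinsic permutation symmetry of the SHG process. Idempotent.
#'
#' @param t a [beta_tensor()]
#' @return a `beta_tensor` with `components[i, j, k] == components[i, k, j]`.
#' @export
symmetrize_shg <- function(t) {
  stopifnot(inherits(t, "beta_tensor"))
  b <- t$components
  t$components <- (b + aperm(b, c(1L, 3L, 2L))) / 2
  t
}

#' @export
print.beta_tensor <- function(x, ...) {
  cat(sprintf("<beta_tensor> frequency = %g eV\n", x$frequency))
  cat(sprintf("  max |component| = %g a.u.\n", max(abs(x$components))))
  invisible(x)
}

#' Rotate a first-hyperpolarizability tensor
#'
#' Applies a rigid rotation to the molecular frame:
#' \eqn{\beta'_{ijk} = \sum_{abc} R_{ia} R_{jb} R_{kc} \beta_{abc}}.
#'
#' @param t a [beta_tensor()]
#' @param R 3x3 proper rotation matrix (orthogonal, det +1; checked to 1e-8)
#' @return the rotated `beta_tensor` (same frequency tag).
#' @export
rotate_tensor <- function(t, R) {
  stopifnot(inherits(t, "beta_tensor"))
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L))) {
    stop("`R` must be a 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop("`R` is not a proper rotation matrix (orthogonal, det +1)",
         call. = FALSE)
  }
  b <- t$components
  # contract one mode at a time; aperm cycles the contracted mode to front
  for (m in 1:3) {
    b <- array(R %*% matrix(b, 3L, 9L), c(3L, 3L, 3L))
    b <- aperm(b, c(2L, 3L, 1L))
  }
  beta_tensor(b, frequency = t$frequency, symmetrize = FALSE)
}

.xyz_letters <- c("x", "y", "z")

.component_keys <- function() {
  g <- expand.grid(k = .xyz_letters, j = .xyz_letters, i = .xyz_letters,
                   stringsAsFactors = FALSE)
  paste0(g$i, g$j, g$k)
}

.key_to_index <- function(key) {
  idx <- match(strsplit(key, "")[[1]], .xyz_letters)
  if (length(idx) != 3L || anyNA(idx)) {
    stop(sprintf("invalid component key '%s'", key), call. = FALSE)
  }
  idx
}

#' Read a beta tensor from a JSON file (`hexanlo-beta-v1` dialect)
#'
#' The dialect is a JSON object with fields `schema` ("hexanlo-beta-v1"),
#' `frequency_eV` (photon energy; defaults to 0 with a warning when absent),
#' optional `sparse` (logical) and `components`, an object keyed by the 27
#' three-letter index strings `"xxx"` .. `"zzz"`. When `sparse` is true,
#' omitted components default to 0; otherwise all 27 keys must be present.
#'
#' @param path path to the JSON file
#' @param symmetrize enforce intrinsic SHG symmetry on read (default TRUE)
#' @return a [beta_tensor()]
#' @export
read_beta_tensor <- function(path, symmetrize = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(doc$schema) && !identical(doc$schema, "hexanlo-beta-v1")) {
    stop(sprintf("unsupported tensor schema '%s' (expected hexanlo-beta-v1)",
                 doc$schema), call. = FALSE)
  }
  if (is.null(doc$frequency_eV)) {
    warning("tensor file has no 'frequency_eV'; assuming static (0 eV)",
            call. = FALSE)
    freq <- 0
  } else {
    freq <- suppressWarnings(as.numeric(doc$frequency_eV))
    if (is.na(freq)) stop("non-numeric value for key 'frequency_eV'",
                          call. = FALSE)
  }
  sparse <- isTRUE(doc$sparse)
  comps <- doc$components
  if (is.null(comps)) stop("tensor file has no 'components' object",
                           call. = FALSE)
  valid <- .component_keys()
  bad <- setdiff(names(comps), valid)
  if (length(bad) > 0) {
    stop(sprintf("unknown component key '%s' in %s", bad[1], path),
         call. = FALSE)
  }
  if (!sparse && length(setdiff(valid, names(comps))) > 0) {
    stop(sprintf("missing component key '%s' (set \"sparse\": true to default absent components to 0)",
                 setdiff(valid, names(comps))[1]), call. = FALSE)
  }
  b <- array(0, c(3L, 3L, 3L))
  for (key in names(comps)) {
    v <- suppressWarnings(as.numeric(comps[[key]]))
    if (length(v) != 1L || is.na(v)) {
      stop(sprintf("non-numeric value for component key '%s'", key),
           call. = FALSE)
    }
    b[t(.key_to_index(key))] <- v
  }
  beta_tensor(b, frequency = freq, symmetrize = symmetrize)
}

#' Write a beta tensor to a JSON file (`hexanlo-beta-v1` dialect)
#'
#' @param t a [beta_tensor()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_beta_tensor <- function(t, path) {
  stopifnot(inherits(t, "beta_tensor"))
  keys <- .component_keys()
  vals <- vapply(keys, function(k) t$components[t(.key_to_index(k))], 0)
  doc <- list(schema = "hexanlo-beta-v1",
              frequency_eV = t$frequency,
              sparse = FALSE,
              components = as.list(vals))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
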