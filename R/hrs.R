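#' Closed-form HRS orientational averages
#'
#' Computes the two isotropic orientational averages
#' \eqn{\langle\beta^2_{ZZZ}\rangle} and \eqn{\langle\beta^2_{ZXX}\rangle}
#' that govern the hyper-Rayleigh-scattering intensity of a freely tumbling
#' molecule. The standard non-Kleinman expressions are used (intrinsic SHG
#' symmetry \eqn{\beta_{ijk}=\beta_{ikj}} assumed, no further index
#' permutation symmetry), with coefficients 1/7, 4/35, 2/35, 1/35, 4/105,
#' 1/105, 2/105 etc. Validate against [mc_rotational_average()] if in doubt.
#'
#' @param t a [beta_tensor()]; symmetrize with [symmetrize_shg()] first if the
#'   raw components are not intrinsically symmetric.
#' @return named numeric vector `c(avg_zzz2 = ..., avg_zxx2 = ...)` in
#'   atomic units squared; both entries are non-negative.
#' @examples
#' b <- array(0, c(3, 3, 3)); b[3, 3, 3] <- 1
#' orientational_averages(beta_tensor(b)) # c(1/7, 1/35)
#' @export
orientational_averages <- function(t) {
  stopifnot(inherits(t, "beta_tensor"))
  b <- t$components
  if (!all(is.finite(b))) stop("tensor components must be finite",
                               call. = FALSE)

  sum2 <- function(f) {            # sum over ordered pairs i != j
    acc <- 0
    for (i in 1:3) for (j in 1:3) if (i != j) acc <- acc + f(i, j)
    acc
  }
  sum3 <- function(f) {            # sum over ordered triples i != j != k (all distinct)
    acc <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) {
      if (i != j && j != k && i != k) acc <- acc + f(i, j, k)
    }
    acc
  }

  zzz2 <-
    (1 / 7)  * sum(diag3(b)^2) +
    (4 / 35) * sum2(function(i, j) b[i, i, j]^2) +
    (2 / 35) * sum2(function(i, j) b[i, i, i] * b[i, j, j]) +
    (4 / 35) * sum2(function(i, j) b[j, i, i] * b[i, i, j]) +
    (4 / 35) * sum2(function(i, j) b[i, i, i] * b[j, j, i]) +
    (1 / 35) * sum2(function(i, j) b[j, i, i]^2) +
    (4 / 105) * sum3(function(i, j, k) b[i, i, j] * b[j, k, k]) +
    (1 / 105) * sum3(function(i, j, k) b[j, i, i] * b[j, k, k]) +
    (4 / 105) * sum3(function(i, j, k) b[i, i, j] * b[k, k, j]) +
    (2 / 105) * sum3(function(i, j, k) b[i, j, k]^2) +
    (4 / 105) * sum3(function(i, j, k) b[i, j, k] * b[j, i, k])

  zxx2 <-
    (1 / 35)  * sum(diag3(b)^2) +
    (4 / 105) * sum2(function(i, j) b[i, i, i] * b[i, j, j]) -
    (2 / 35)  * sum2(function(i, j) b[i, i, i] * b[j, j, i]) +
    (8 / 105) * sum2(function(i, j) b[i, i, j]^2) +
    (3 / 35)  * sum2(function(i, j) b[i, j, j]^2) -
    (2 / 35)  * sum2(function(i, j) b[i, i, j] * b[j, i, i]) +
    (1 / 35)  * sum3(function(i, j, k) b[i, j, j] * b[i, k, k]) -
    (2 / 105) * sum3(function(i, j, k) b[i, i, k] * b[j, j, k]) -
    (2 / 105) * sum3(function(i, j, k) b[i, i, j] * b[j, k, k]) +
    (2 / 35)  * sum3(function(i, j, k) b[i, j, k]^2) -
    (2 / 105) * sum3(function(i, j, k) b[i, j, k] * b[j, i, k])

  c(avg_zzz2 = zzz2, avg_zxx2 = zxx2)
}

diag3 <- function(b) c(b[1, 1, 1], b[2, 2, 2], b[3, 3, 3])

#' Hyper-Rayleigh-scattering first hyperpolarizability
#'
#' \eqn{\beta_{HRS} = \sqrt{\langle\beta^2_{ZZZ}\rangle +
#' \langle\beta^2_{ZXX}\rangle}}, the rotational invariant measured in an HRS
#' experiment with detection perpendicular to the propagation plane. The
#' square root keeps \eqn{\beta_{HRS}} in atomic units of \eqn{\beta}; the
#' depolarization ratio is
#' \eqn{\langle\beta^2_{ZZZ}\rangle / \langle\beta^2_{ZXX}\rangle}.
#'
#' A centrosymmetric structure has an identically zero tensor and hence
#' \eqn{\beta_{HRS} = 0}.
#'
#' @param t a [beta_tensor()]
#' @return list of class `hrs_result` with `beta_hrs`, `avg_zzz2`,
#'   `avg_zxx2`, `depolarization_ratio` (NA when
#'   \eqn{\langle\beta^2_{ZXX}\rangle = 0}) and `frequency`.
#' @export
beta_hrs <- function(t) {
  av <- orientational_averages(t)
  dr <- if (av[["avg_zxx2"]] > 0) av[["avg_zzz2"]] / av[["avg_zxx2"]] else NA_real_
  structure(list(beta_hrs = sqrt(av[["avg_zzz2"]] + av[["avg_zxx2"]]),
                 avg_zzz2 = av[["avg_zzz2"]],
                 avg_zxx2 = av[["avg_zxx2"]],
                 depolarization_ratio = dr,
                 frequency = t$frequency),
            class = "hrs_result")
}

#' @export
print.hrs_result <- function(x, ...) {
  cat(sprintf("beta_HRS = %.6g a.u. (frequency %g eV)\n", x$beta_hrs,
              x$frequency))
  cat(sprintf("  <beta2_ZZZ> = %.6g  <beta2_ZXX> = %.6g  DR = %.4g\n",
              x$avg_zzz2, x$avg_zxx2, x$depolarization_ratio))
  invisible(x)
}

#' Haar-uniform random rotation matrices
#'
#' Draws unit quaternions from the normalized 4D Gaussian, which guarantees
#' Haar (uniform) sampling of SO(3).
#'
#' @param n number of rotations
#' @return 3x3xn array of rotation matrices.
#' @keywords internal
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  R[1, 2, ] <- 2 * (x * y - w * z)
  R[1, 3, ] <- 2 * (x * z + w * y)
  R[2, 1, ] <- 2 * (x * y + w * z)
  R[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  R[2, 3, ] <- 2 * (y * z - w * x)
  R[3, 1, ] <- 2 * (x * z - w * y)
  R[3, 2, ] <- 2 * (y * z + w * x)
  R[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  R
}

# laboratory Z and X rows of n Haar-uniform rotations, as n x 3 matrices
.random_rotation_rows <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  list(X = cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
       Z = cbind(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Monte-Carlo rotational averaging oracle
#'
#' Brute-force estimate of the HRS orientational averages: draws Haar-uniform
#' random 3D rotations, evaluates the laboratory-frame components
#' \eqn{\beta'_{ZZZ}} and \eqn{\beta'_{ZXX}} of the rotated tensor, and
#' averages their squares. Converges to [orientational_averages()] as
#' `n_samples` grows; serves as an independent verification oracle for the
#' closed-form coefficients.
#'
#' @param t a [beta_tensor()]
#' @param n_samples number of random orientations (>= 1)
#' @param seed integer seed; the caller's RNG state is left untouched
#' @param chunk_size orientations per vectorized block (memory knob)
#' @return list with `avg_zzz2`, `avg_zxx2`, their Monte-Carlo standard
#'   errors `se_zzz2`, `se_zxx2`, and `n_samples`.
#' @export
mc_rotational_average <- function(t, n_samples, seed, chunk_size = 200000L) {
  stopifnot(inherits(t, "beta_tensor"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("`n_samples` must be a positive integer", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  M <- matrix(t$components, 3L, 9L)     # rows: first index a; cols: (b, c)
  s1 <- s2 <- ss1 <- ss2 <- 0
  done <- 0L
  while (done < n_samples) {
    m <- min(chunk_size, n_samples - done)
    rows <- .random_rotation_rows(m)
    Z <- rows$Z; X <- rows$X
    A <- Z %*% M                        # contract first index with lab Z
    bzzz <- bzxx <- numeric(m)
    for (cc in 1:3) {                   # contract second index
      blk <- A[, (3 * cc - 2):(3 * cc), drop = FALSE]
      bzzz <- bzzz + rowSums(blk * Z) * Z[, cc]
      bzxx <- bzxx + rowSums(blk * X) * X[, cc]
    }
    s1 <- s1 + sum(bzzz^2);  ss1 <- ss1 + sum(bzzz^4)
    s2 <- s2 + sum(bzxx^2);  ss2 <- ss2 + sum(bzxx^4)
    done <- done + m
  }
  n <- as.double(n_samples)
  m1 <- s1 / n; m2 <- s2 / n
  v1 <- max(ss1 / n - m1^2, 0); v2 <- max(ss2 / n - m2^2, 0)
  list(avg_zzz2 = m1, avg_zxx2 = m2,
       se_zzz2 = sqrt(v1 / n), se_zxx2 = sqrt(v2 / n),
       n_samples = n_samples)
}
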