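#' Read a macrocycle geometry (XYZ + ring sidecar)
#'
#' Reads a standard XYZ file (atom count, comment line, `element x y z`
#' records in Angstrom) together with a JSON sidecar declaring the
#' heterocycle rings: `{"rings": [[...], ...], "path": [...]}` with 1-based
#' atom indices, rings listed in macrocycle order (each ring is a neighbor of
#' the next, wrapping around). The optional `path` lists the annulene
#' conjugation pathway.
#'
#' @param xyz_path path to the XYZ file
#' @param rings_path path to the JSON sidecar
#' @return object of class `macrocycle_geometry`: list with `elements`
#'   (character), `coordinates` (n x 3 matrix, Angstrom), `rings` (list of
#'   integer vectors) and `path` (integer vector or NULL).
#' @export
read_xyz <- function(xyz_path, rings_path) {
  lines <- readLines(xyz_path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed XYZ file: too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("malformed XYZ file: bad atom count",
                               call. = FALSE)
  if (length(lines) < n + 2L) stop("malformed XYZ file: truncated",
                                   call. = FALSE)
  recs <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    f <- recs[[i]]
    if (length(f) < 4L) stop(sprintf("malformed XYZ atom line %d", i),
                             call. = FALSE)
    elements[i] <- f[1]
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(xyz)) stop(sprintf("non-numeric coordinate on atom line %d", i),
                         call. = FALSE)
    coords[i, ] <- xyz
  }
  side <- jsonlite::read_json(rings_path, simplifyVector = TRUE)
  if (is.null(side$rings)) stop("sidecar declares no rings", call. = FALSE)
  rings <- unname(lapply(if (is.list(side$rings)) side$rings else
                           split(side$rings, row(side$rings)),
                         function(v) as.integer(v)))
  path <- if (!is.null(side$path)) as.integer(side$path) else NULL
  macrocycle_geometry(elements, coords, rings, path)
}

#' Construct and validate a macrocycle geometry
#'
#' @param elements character vector of element symbols
#' @param coordinates n x 3 numeric matrix (Angstrom)
#' @param rings list of integer index vectors (1-based), macrocycle order
#' @param path optional conjugation-pathway indices
#' @return object of class `macrocycle_geometry`.
#' @export
macrocycle_geometry <- function(elements, coordinates, rings, path = NULL) {
  coordinates <- as.matrix(coordinates)
  n <- length(elements)
  stopifnot(is.matrix(coordinates), ncol(coordinates) == 3L,
            nrow(coordinates) == n, all(is.finite(coordinates)))
  for (r in seq_along(rings)) {
    idx <- rings[[r]]
    if (length(idx) < 4L) {
      stop(sprintf("ring %d has fewer than 4 atoms", r), call. = FALSE)
    }
    if (any(idx < 1L | idx > n)) {
      stop(sprintf("ring %d references an atom index outside 1..%d (indices are 1-based)",
                   r, n), call. = FALSE)
    }
  }
  if (!is.null(path) && any(path < 1L | path > n)) {
    stop("conjugation path references an out-of-range atom index",
         call. = FALSE)
  }
  structure(list(elements = elements, coordinates = coordinates,
                 rings = rings, path = path),
            class = "macrocycle_geometry")
}

#' Write a macrocycle geometry back to XYZ (+ sidecar)
#'
#' @param g a [macrocycle_geometry()]
#' @param xyz_path,rings_path output paths
#' @param comment XYZ comment line
#' @return `xyz_path`, invisibly.
#' @export
write_xyz <- function(g, xyz_path, rings_path = NULL, comment = "hexanlo") {
  stopifnot(inherits(g, "macrocycle_geometry"))
  lines <- c(as.character(length(g$elements)), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f", g$elements,
                     g$coordinates[, 1], g$coordinates[, 2],
                     g$coordinates[, 3]))
  writeLines(lines, xyz_path)
  if (!is.null(rings_path)) {
    jsonlite::write_json(list(rings = g$rings, path = g$path), rings_path,
                         auto_unbox = FALSE, digits = NA, null = "null")
  }
  invisible(xyz_path)
}

# unit normal of the total-least-squares plane through a ring
.ring_normal <- function(coords, idx) {
  P <- coords[idx, , drop = FALSE]
  C <- sweep(P, 2, colMeans(P))
  sv <- svd(C)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) ring: plane fit undefined", call. = FALSE)
  }
  sv$v[, 3]
}

.ring_normals <- function(g) {
  vapply(g$rings, function(idx) .ring_normal(g$coordinates, idx),
         numeric(3))                      # 3 x n_rings
}

#' Torsional ring strain
#'
#' Mean dihedral angle between neighboring heterocycle ring planes: for each
#' cyclic neighbor pair the unsigned angle in \[0, 90\] degrees between the
#' total-least-squares ring planes, averaged around the macrocycle. Planar
#' macrocycles give small values; substituent crowding and Moebius twisting
#' drive it up.
#'
#' @param g a [macrocycle_geometry()] with at least 2 rings
#' @return mean inter-ring plane angle in degrees.
#' @export
phi_p <- function(g) {
  stopifnot(inherits(g, "macrocycle_geometry"))
  N <- .ring_normals(g)
  m <- ncol(N)
  if (m < 2L) stop("phi_p needs at least 2 rings", call. = FALSE)
  nxt <- c(2:m, 1L)
  ang <- vapply(seq_len(m), function(k) {
    d <- abs(sum(N[, k] * N[, nxt[k]]))
    acos(min(1, d)) * 180 / pi
  }, 0)
  mean(ang)
}

#' Signed pi-conjugation index
#'
#' Measures how effectively neighboring p-orbitals overlap around the
#' macrocycle: the product over cyclic neighbor pairs of the cosine between
#' consecutively orientation-propagated ring normals. Because every ring
#' normal enters the cyclic product exactly twice, the result does not
#' depend on the arbitrary sign of each fitted normal. An untwisted
#' (Hueckel) loop gives a positive value approaching 1 for a planar
#' macrocycle; a single orientation reversal around the loop (Moebius)
#' makes the product negative. |value| <= 1 always.
#'
#' @param g a [macrocycle_geometry()] with at least 2 rings
#' @return signed dimensionless index in \[-1, 1\].
#' @export
pi_index <- function(g) {
  stopifnot(inherits(g, "macrocycle_geometry"))
  N <- .ring_normals(g)
  m <- ncol(N)
  if (m < 2L) stop("pi_index needs at least 2 rings", call. = FALSE)
  nxt <- c(2:m, 1L)
  prod(vapply(seq_len(m), function(k) sum(N[, k] * N[, nxt[k]]), 0))
}

#' Classify macrocycle topology from the pi-conjugation index
#'
#' Positive index: untwisted Hueckel loop. Negative: singly-twisted Moebius
#' loop (one p-orbital phase reversal). Zero is indeterminate (orthogonal
#' neighbor planes).
#'
#' @param pi_value a [pi_index()] value
#' @return `"Hueckel"` or `"Moebius"`.
#' @export
classify_topology <- function(pi_value) {
  if (!is.finite(pi_value) || pi_value == 0) {
    stop("topology indeterminate for pi index 0", call. = FALSE)
  }
  if (pi_value > 0) "Hueckel" else "Moebius"
}

#' Inversion-center detection
#'
#' Tests whether the structure is centrosymmetric: with the centroid as the
#' candidate inversion center, every atom must map under inversion onto an
#' atom of the same element within `tol` (bijective matching, greedy nearest
#' neighbor with verification). Centrosymmetric (Ci) structures have an
#' identically zero first hyperpolarizability, hence beta_HRS = 0.
#'
#' @param g a [macrocycle_geometry()] (or any >= 2-atom structure)
#' @param tol matching tolerance in Angstrom
#' @return list with `centrosymmetric` (logical) and `center` (length-3).
#' @export
detect_inversion_center <- function(g, tol = 0.1) {
  stopifnot(inherits(g, "macrocycle_geometry"))
  X <- g$coordinates
  if (nrow(X) < 2L) stop("need at least 2 atoms", call. = FALSE)
  center <- colMeans(X)
  Y <- sweep(-sweep(X, 2, center), 2, -center)   # 2*center - X
  used <- rep(FALSE, nrow(X))
  ok <- TRUE
  for (i in seq_len(nrow(X))) {
    cand <- which(!used & g$elements == g$elements[i])
    if (length(cand) == 0L) { ok <- FALSE; break }
    d2 <- rowSums((X[cand, , drop = FALSE] -
                     matrix(Y[i, ], length(cand), 3, byrow = TRUE))^2)
    j <- cand[which.min(d2)]
    if (sqrt(min(d2)) > tol) { ok <- FALSE; break }
    used[j] <- TRUE
  }
  list(centrosymmetric = ok, center = center)
}

#' All topology descriptors of a geometry
#'
#' @param g a [macrocycle_geometry()]
#' @param aromatic_threshold pi-index threshold above which a Hueckel
#'   macrocycle is flagged aromatic (default 0.30)
#' @param inversion_tol tolerance for [detect_inversion_center()] (Angstrom)
#' @return list with `phi_p`, `pi_index`, `topology`, `aromatic_by_pi`,
#'   `centrosymmetric`.
#' @export
topology_descriptors <- function(g, aromatic_threshold = 0.30,
                                 inversion_tol = 0.1) {
  pv <- pi_index(g)
  list(phi_p = phi_p(g),
       pi_index = pv,
       topology = classify_topology(pv),
       aromatic_by_pi = pv >= aromatic_threshold,
       centrosymmetric = detect_inversion_center(g, inversion_tol)$centrosymmetric)
}

# solve for a unit vector at angle theta_a from unit `a` and theta_b from
# unit `b` (two-cone intersection); all angles in radians
.cone_intersection <- function(a, b, theta_a, theta_b) {
  gab <- sum(a * b)
  if (abs(abs(gab) - 1) < 1e-12) {      # a and b (anti)parallel
    if (abs(theta_a - ifelse(gab > 0, theta_b, pi - theta_b)) > 1e-9) {
      stop("inter-ring twist sequence is geometrically infeasible",
           call. = FALSE)
    }
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * a) * a
    u <- u / sqrt(sum(u^2))
    return(cos(theta_a) * a + sin(theta_a) * u)
  }
  M <- matrix(c(1, gab, gab, 1), 2, 2)
  ab <- solve(M, c(cos(theta_a), cos(theta_b)))
  e <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  e <- e / sqrt(sum(e^2))
  c2 <- 1 - (ab[1]^2 + ab[2]^2 + 2 * ab[1] * ab[2] * gab)
  if (c2 < -1e-9) {
    stop("inter-ring twist sequence is geometrically infeasible",
         call. = FALSE)
  }
  v <- ab[1] * a + ab[2] * b + sqrt(max(c2, 0)) * e
  v / sqrt(sum(v^2))
}

#' Synthetic hexaphyrin-like geometry generator
#'
#' Builds an idealized macrocycle frame for testing the geometry
#' descriptors without DFT coordinates: six regular pentagon rings (one
#' nitrogen, four carbons each) centered on a circle, with prescribed
#' inter-ring plane angles.
#'
#' For `moebius = FALSE` the six ring normals are constructed so that the
#' angle between each cyclic neighbor pair of ring planes equals the
#' corresponding entry of `twists` exactly (signs of intermediate tilts are
#' searched, then the last normal closes the loop on a two-cone
#' intersection; an infeasible angle sequence errors). For `moebius = TRUE`
#' the normal tilts outward and rotates by 180 degrees in total around the
#' loop — the classic singly-twisted band, whose propagated-orientation
#' product (the pi index) is negative; `twists` is ignored in that mode.
#'
#' @param twists six inter-ring plane angles in degrees (Hueckel mode)
#' @param moebius build the singly-twisted frame instead
#' @param ring_radius pentagon circumradius (Angstrom)
#' @param macro_radius macrocycle circumradius (Angstrom)
#' @return a [macrocycle_geometry()] of 30 atoms in 6 rings.
#' @export
synthetic_hexaphyrin <- function(twists = rep(0, 6), moebius = FALSE,
                                 ring_radius = 1.2, macro_radius = 4.0) {
  n_r <- 6L
  if (moebius) {
    psi <- (seq_len(n_r) - 1L) * pi / n_r     # 0..150 deg: one half-turn
    centers_ang <- (seq_len(n_r) - 1L) * 2 * pi / n_r
    normals <- vapply(seq_len(n_r), function(k) {
      radial <- c(cos(centers_ang[k]), sin(centers_ang[k]), 0)
      cos(psi[k]) * c(0, 0, 1) + sin(psi[k]) * radial
    }, numeric(3))
  } else {
    stopifnot(length(twists) == 6L, all(is.finite(twists)),
              all(twists >= 0), all(twists <= 90))
    th <- twists * pi / 180
    normals <- NULL
    for (signs in asplit(as.matrix(expand.grid(rep(list(c(1, -1)), 4L))), 1)) {
      phi <- cumsum(c(0, signs * th[1:4]))
      cand <- vapply(phi, function(p) c(sin(p), 0, cos(p)), numeric(3))
      # n6 must sit at th[5] from ring 5 and th[6] from ring 1
      n6 <- tryCatch(.cone_intersection(cand[, 5], cand[, 1], th[5], th[6]),
                     error = function(e) NULL)
      if (!is.null(n6)) { normals <- cbind(cand, n6); break }
    }
    if (is.null(normals)) {
      stop("inter-ring twist sequence is geometrically infeasible",
           call. = FALSE)
    }
  }
  elements <- character(0)
  coords <- NULL
  for (k in seq_len(n_r)) {
    ang <- (k - 1L) * 2 * pi / n_r
    center <- macro_radius * c(cos(ang), sin(ang), 0)
    n <- normals[, k]
    ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * n) * n
    u <- u / sqrt(sum(u^2))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    t5 <- 2 * pi * (0:4) / 5
    pts <- t(center + ring_radius * (outer(u, cos(t5)) + outer(v, sin(t5))))
    coords <- rbind(coords, pts)
    elements <- c(elements, c("N", "C", "C", "C", "C"))
  }
  rings <- split(seq_len(5L * n_r), rep(seq_len(n_r), each = 5L))
  macrocycle_geometry(elements, coords, unname(rings))
}
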