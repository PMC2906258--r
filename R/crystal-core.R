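# Unit-cell and symmetry mathematics: coordinate conversions, d-spacings,
# asymmetric-unit mapping, centric/epsilon classification, ADP tensors.

#' Fractional/Cartesian coordinate conversion
#'
#' PDB orthogonalization convention: a along x, b in the xy-plane. The two
#' functions are exact inverses.
#'
#' @param x n x 3 matrix (or length-3 vector) of coordinates.
#' @param frame a [CrystalFrame-class].
#' @return n x 3 matrix of converted coordinates.
#' @export
fracToCart <- function(x, frame) {
  x <- rbind(x)
  x %*% t(frame@orth)
}

#' @rdname fracToCart
#' @export
cartToFrac <- function(x, frame) {
  x <- rbind(x)
  x %*% t(frame@frac)
}

#' Resolution of Miller indices
#'
#' d = 1 / |s| with s the reciprocal-space vector of h.
#'
#' @param h n x 3 integer matrix (or length-3 vector) of Miller indices.
#' @param frame a [CrystalFrame-class].
#' @return numeric vector of d-spacings in Angstrom.
#' @export
dSpacing <- function(h, frame) {
  h <- rbind(h)
  if (any(rowSums(abs(h)) == 0)) stop("d-spacing undefined for (0,0,0)")
  s <- .recipVectors(h, frame)
  unname(1 / sqrt(rowSums(s * s)))
}

# Rotation parts acting on Miller indices: h' = t(R) h, i.e. row-vector
# h %*% R. Returned as the matrices to right-multiply row Miller indices by.
.millerRotations <- function(frame) {
  Rs <- lapply(frame@symops, function(o) round(o$R))
  keys <- vapply(Rs, function(R) paste(R, collapse = ","), character(1))
  Rs[!duplicated(keys)]
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' All symmetry-equivalent indices (and, unless `anomalous`, Friedel mates)
#' map to the same canonical triple: the lexicographically greatest
#' equivalent, compared on h then k then l.
#'
#' @param h n x 3 matrix of Miller indices.
#' @param frame a [CrystalFrame-class].
#' @param anomalous if TRUE, Friedel mates are kept distinct.
#' @return list with `miller` (canonical n x 3), `opIndex` (which rotation
#'   produced the representative) and `conjugate` (TRUE where the Friedel
#'   mate was taken).
#' @export
mapToAsu <- function(h, frame, anomalous = FALSE) {
  h <- rbind(h)
  rots <- .millerRotations(frame)
  n <- nrow(h); nr <- length(rots)
  # images: array n x 3 x (nr or 2nr)
  best <- matrix(-Inf, n, 3)
  bestOp <- integer(n); bestConj <- logical(n)
  score <- function(m) (m[, 1] * 4096 + m[, 2]) * 4096 + m[, 3]
  bestScore <- rep(-Inf, n)
  for (i in seq_len(nr)) {
    for (cj in c(FALSE, if (!anomalous) TRUE)) {
      img <- h %*% rots[[i]]
      if (cj) img <- -img
      sc <- score(img)
      upd <- sc > bestScore
      if (any(upd)) {
        best[upd, ] <- img[upd, , drop = FALSE]
        bestOp[upd] <- i; bestConj[upd] <- cj; bestScore[upd] <- sc[upd]
      }
    }
  }
  list(miller = best, opIndex = bestOp, conjugate = bestConj)
}

#' Centric flag and epsilon multiplicity of reflections
#'
#' A reflection is centric when some symmetry rotation maps h to -h; epsilon
#' counts the rotations that fix h.
#'
#' @inheritParams mapToAsu
#' @return list with logical `centric` and integer `epsilon`.
#' @export
centricEpsilon <- function(h, frame) {
  h <- rbind(h)
  rots <- .millerRotations(frame)
  n <- nrow(h)
  centric <- logical(n); eps <- integer(n)
  for (R in rots) {
    img <- h %*% R
    eps <- eps + as.integer(rowSums(img == h) == 3L)
    centric <- centric | (rowSums(img == -h) == 3L)
  }
  list(centric = centric, epsilon = eps)
}

#' Systematic-absence test
#'
#' h is absent when a symmetry operation fixes h but shifts its phase:
#' t(R) h == h with exp(2 pi i h.t) != 1.
#'
#' @inheritParams mapToAsu
#' @return logical vector.
#' @export
isSystematicAbsence <- function(h, frame) {
  h <- rbind(h)
  absent <- logical(nrow(h))
  for (op in frame@symops) {
    img <- h %*% round(op$R)
    fixes <- rowSums(img == h) == 3L
    phase <- (h %*% op$t) %% 1
    absent <- absent | (fixes & pmin(phase, 1 - phase) > 1e-9)
  }
  absent
}

#' Positive-definiteness of an ADP tensor
#'
#' TRUE iff the smallest eigenvalue exceeds 1e-9 Angstrom^2, so that an
#' exactly zero displacement parameter — a frequent deposition artefact for
#' H atoms — counts as nonphysical.
#'
#' @param u symmetric 3x3 matrix (Cartesian U, Angstrom^2), or a length-6
#'   vector (u11, u22, u33, u12, u13, u23).
#' @param tol eigenvalue tolerance.
#' @return logical.
#' @export
isPositiveDefinite <- function(u, tol = 1e-9) {
  if (is.numeric(u) && length(u) == 6)
    u <- matrix(c(u[1], u[4], u[5], u[4], u[2], u[6], u[5], u[6], u[3]), 3, 3)
  if (max(abs(u - t(u))) > 1e-8) stop("ADP tensor must be symmetric")
  min(eigen(u, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# 6-vector (u11,u22,u33,u12,u13,u23) <-> symmetric matrix helpers
.uVecToMat <- function(v)
  matrix(c(v[1], v[4], v[5], v[4], v[2], v[6], v[5], v[6], v[3]), 3, 3)
.uMatToVec <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' B factor / isotropic U conversion (B = 8 pi^2 u)
#' @param b,u numeric.
#' @export
bToU <- function(b) b / (8 * pi^2)

#' @rdname bToU
#' @export
uToB <- function(u) u * 8 * pi^2
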