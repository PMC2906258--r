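# Structure factors from an atomic model, by direct summation and by FFT
# sampling of a model density, for X-ray and neutron scattering; flat
# bulk-solvent mask construction and its Fourier transform.

#' Enumerate the unique Miller indices to a resolution limit
#'
#' Brute-force enumeration over the index box, mapped to canonical
#' asymmetric-unit representatives; systematic absences and (0,0,0) are
#' excluded.
#'
#' @param frame a [CrystalFrame-class].
#' @param dMin high-resolution limit, Angstrom.
#' @param dMax low-resolution limit (default Inf).
#' @param anomalous keep Friedel mates distinct.
#' @return integer matrix n x 3, sorted.
#' @export
millerSet <- function(frame, dMin, dMax = Inf, anomalous = FALSE) {
  lens <- sqrt(colSums(frame@orth^2))
  hmax <- floor(lens / dMin) + 1L
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- dSpacing(grid, frame)
  grid <- grid[d >= dMin & d <= dMax, , drop = FALSE]
  asu <- mapToAsu(grid, frame, anomalous = anomalous)$miller
  asu <- asu[!duplicated(asu), , drop = FALSE]
  asu <- asu[!isSystematicAbsence(asu, frame), , drop = FALSE]
  asu[order(-asu[, 1], -asu[, 2], -asu[, 3]), , drop = FALSE]
}

# Flatten all models of an ensemble into one atom table with fractional
# coordinates and the per-atom Cartesian U (NA rows for isotropic atoms).
.flatAtoms <- function(ensemble) {
  tab <- do.call(rbind, ensemble@models)
  xyzf <- cartToFrac(as.matrix(tab[, c("x", "y", "z")]), ensemble@frame)
  list(tab = tab, xyzFrac = xyzf, aniso = !is.na(tab$u11))
}

#' Structure factors by direct summation
#'
#' F(h) = sum over symops, models and atoms of
#' occ * f(s) * DW * exp(2 pi i (t(R) h . x + h . t)), with the isotropic
#' Debye-Waller factor exp(-B s^2/4) or the anisotropic
#' exp(-2 pi^2 s' U_cart s). Multiple models are summed directly: their
#' occupancies encode the ensemble weighting. Optional anomalous corrections
#' f' and f'' are added per scattering type.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param miller n x 3 integer matrix of Miller indices.
#' @param mode "xray" or "neutron".
#' @param fpfdp optional named list: scattering type -> c(fp, fdp).
#' @return complex vector of structure factors (electrons, or scattering
#'   lengths in neutron mode).
#' @export
fcalcDirect <- function(ensemble, miller, mode = c("xray", "neutron"),
                        fpfdp = NULL) {
  mode <- match.arg(mode)
  frame <- ensemble@frame
  miller <- rbind(miller)
  fl <- .flatAtoms(ensemble)
  tab <- fl$tab
  s2 <- rowSums(.recipVectors(miller, frame)^2)
  f0 <- scatteringFactors(tab$scatter, s2, mode)   # n x natoms
  fdp <- numeric(length(tab$scatter))
  if (!is.null(fpfdp)) {
    for (ty in names(fpfdp)) {
      sel <- toupper(tab$scatter) == toupper(ty)
      f0[, sel] <- f0[, sel] + fpfdp[[ty]][1]
      fdp[sel] <- fpfdp[[ty]][2]
    }
  }
  occ <- tab$occ
  anis <- fl$aniso
  U6 <- as.matrix(tab[, c("u11", "u22", "u33", "u12", "u13", "u23")])
  Fre <- numeric(nrow(miller)); Fim <- numeric(nrow(miller))
  for (op in frame@symops) {
    hop <- miller %*% op$R                       # t(R) h as rows
    sop <- .recipVectors(hop, frame)
    dw <- matrix(0, nrow(miller), nrow(tab))
    if (any(!anis))
      dw[, !anis] <- exp(-outer(s2 / 4, tab$b[!anis]))
    if (any(anis)) {
      M6 <- cbind(sop[, 1]^2, sop[, 2]^2, sop[, 3]^2,
                  2 * sop[, 1] * sop[, 2], 2 * sop[, 1] * sop[, 3],
                  2 * sop[, 2] * sop[, 3])
      dw[, anis] <- exp(-2 * pi^2 * (M6 %*% t(U6[anis, , drop = FALSE])))
    }
    phase <- 2 * pi * (hop %*% t(fl$xyzFrac) +
                       as.numeric(miller %*% op$t))
    A <- f0 * dw * rep(occ, each = nrow(miller))
    cp <- cos(phase); sp <- sin(phase)
    Fre <- Fre + rowSums(A * cp)
    Fim <- Fim + rowSums(A * sp)
    if (any(fdp != 0)) {
      Bc <- dw * rep(occ * fdp, each = nrow(miller))
      Fre <- Fre - rowSums(Bc * sp)
      Fim <- Fim + rowSums(Bc * cp)
    }
  }
  complex(real = Fre, imaginary = Fim)
}

# FFT-friendly grid dimensions with spacing <= dMin/factor along each axis.
.gridDims <- function(frame, dMin, factor = 4) {
  lens <- sqrt(colSums(frame@orth^2))
  vapply(lens, function(l) stats::nextn(ceiling(factor * l / dMin), c(2, 3, 5)),
         integer(1))
}

# Expand atoms by all symmetry operators; returns fractional coords wrapped
# into [0,1) and rotated Cartesian U (or NA) per image.
.symExpandAtoms <- function(ensemble) {
  fl <- .flatAtoms(ensemble)
  frame <- ensemble@frame
  out <- list()
  for (op in frame@symops) {
    xf <- (fl$xyzFrac %*% t(op$R) + rep(op$t, each = nrow(fl$xyzFrac))) %% 1
    Rc <- .cartRotation(op$R, frame)
    U <- lapply(seq_len(nrow(fl$tab)), function(i) {
      if (!fl$aniso[i]) return(NULL)
      Rc %*% .uVecToMat(as.numeric(fl$tab[i, c("u11", "u22", "u33",
                                               "u12", "u13", "u23")])) %*% t(Rc)
    })
    out[[length(out) + 1L]] <- list(xf = xf, U = U)
  }
  list(images = out, tab = fl$tab, aniso = fl$aniso)
}

# Local voxel box around a fractional centre: grid index triples (0-based,
# wrapped) and Cartesian displacement vectors from the centre.
.voxelBox <- function(centerFrac, radius, frame, dims) {
  rowNorms <- sqrt(rowSums(frame@frac^2))
  dfrac <- radius * rowNorms
  lo <- floor((centerFrac - dfrac) * dims)
  hi <- ceiling((centerFrac + dfrac) * dims)
  idx <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  gfrac <- cbind(idx$i / dims[1], idx$j / dims[2], idx$k / dims[3])
  diff <- gfrac - rep(centerFrac, each = nrow(gfrac))
  dcart <- diff %*% t(frame@orth)
  wrapped <- cbind(idx$i %% dims[1], idx$j %% dims[2], idx$k %% dims[3])
  list(flat = 1L + wrapped[, 1] + dims[1] * (wrapped[, 2] + dims[2] * wrapped[, 3]),
       dcart = dcart)
}

#' Structure factors by FFT density sampling
#'
#' Atoms are sampled as sums of Gaussians on a unit-cell grid (spacing at
#' most dMin/4), each term truncated where its density falls below 1e-6 of
#' the peak; an extra smearing B is added during sampling and removed
#' analytically in reciprocal space to suppress aliasing. The inverse FFT of
#' the sampled density yields F(h).
#'
#' @inheritParams fcalcDirect
#' @param dMin resolution limit defining the grid.
#' @param gridFactor grid sampling rate (grid spacing = dMin / gridFactor).
#' @param bExtra anti-aliasing smearing B in Angstrom^2.
#' @return complex vector of structure factors for `miller`.
#' @export
fcalcFft <- function(ensemble, miller, dMin, mode = c("xray", "neutron"),
                     gridFactor = 4, bExtra = 20) {
  mode <- match.arg(mode)
  if (gridFactor < 4) stop("grid too coarse: spacing must be <= dMin/4")
  frame <- ensemble@frame
  miller <- rbind(miller)
  dims <- .gridDims(frame, dMin, gridFactor)
  rho <- array(0, dims)
  ex <- .symExpandAtoms(ensemble)
  tab <- ex$tab
  logCut <- log(1e6)
  for (img in ex$images) {
    for (i in seq_len(nrow(tab))) {
      if (tab$occ[i] == 0) next
      if (mode == "neutron") {
        amp <- .NEUTRON_B[[tab$scatter[i]]]
        aTerms <- amp; bTerms <- 0
      } else {
        ff <- .XRAY_FF[[toupper(tab$scatter[i])]]
        aTerms <- c(ff$a, ff$c); bTerms <- c(ff$b, 0)
      }
      occ <- tab$occ[i]
      if (!ex$aniso[i]) {
        bp <- bTerms + tab$b[i] + bExtra
        rcut <- sqrt(max(bp) * logCut) / (2 * pi)
        box <- .voxelBox(img$xf[i, ], rcut, frame, dims)
        r2 <- rowSums(box$dcart^2)
        dens <- numeric(length(r2))
        for (j in seq_along(aTerms))
          dens <- dens + aTerms[j] * (4 * pi / bp[j])^1.5 *
            exp(-4 * pi^2 * r2 / bp[j])
        rho[box$flat] <- rho[box$flat] + occ * dens
      } else {
        U <- img$U[[i]]
        for (j in seq_along(aTerms)) {
          Ut <- U + diag(3) * (bTerms[j] + bExtra) / (8 * pi^2)
          eg <- eigen(Ut, symmetric = TRUE)
          rcut <- sqrt(2 * max(eg$values) * logCut)
          box <- .voxelBox(img$xf[i, ], rcut, frame, dims)
          Uinv <- eg$vectors %*% diag(1 / eg$values) %*% t(eg$vectors)
          q <- rowSums((box$dcart %*% Uinv) * box$dcart)
          dens <- aTerms[j] * (2 * pi)^-1.5 / sqrt(prod(eg$values)) *
            exp(-q / 2)
          rho[box$flat] <- rho[box$flat] + occ * dens
        }
      }
    }
  }
  Fgrid <- fft(rho, inverse = TRUE) * (cellVolume(frame) / prod(dims))
  idx <- 1L + (miller[, 1] %% dims[1]) +
    dims[1] * ((miller[, 2] %% dims[2]) + dims[2] * (miller[, 3] %% dims[3]))
  s2 <- rowSums(.recipVectors(miller, frame)^2)
  Fgrid[idx] * exp(bExtra * s2 / 4)
}

#' Flat bulk-solvent mask
#'
#' Two-stage mask on a unit-cell grid: a voxel belongs to the protein region
#' when it lies within (r_vdw + rSolv) of any atom (symmetry images
#' included); then every protein voxel farther than r_vdw from all atoms but
#' within rShrink of a solvent voxel is reassigned to solvent
#' (shrink-truncation). H and D atoms do not contribute. Defaults follow the
#' shipped convention rSolv = 1.11, rShrink = 0.9.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param dMin resolution used to choose the grid (spacing dMin/4), or pass
#'   `dims` directly.
#' @param rSolv probe radius, Angstrom.
#' @param rShrink shrink radius, Angstrom.
#' @param dims optional explicit grid dimensions.
#' @return a [SolventMask-class].
#' @export
solventMask <- function(ensemble, dMin = 2, rSolv = 1.11, rShrink = 0.9,
                        dims = NULL) {
  frame <- ensemble@frame
  if (is.null(dims)) dims <- .gridDims(frame, dMin, 4)
  dims <- as.integer(dims)
  ntot <- prod(dims)
  protein <- logical(ntot); core <- logical(ntot)
  ex <- .symExpandAtoms(ensemble)
  keep <- !(ex$tab$element %in% c("H", "D"))
  if (!any(keep)) {
    warning("no non-hydrogen atoms: all-solvent mask")
    m <- array(TRUE, dims)
    return(new("SolventMask", grid = dims, solvent = m, fraction = 1))
  }
  rv <- vdwRadius(ex$tab$element)
  for (img in ex$images) {
    for (i in which(keep)) {
      box <- .voxelBox(img$xf[i, ], rv[i] + rSolv, frame, dims)
      d2 <- rowSums(box$dcart^2)
      protein[box$flat[d2 <= (rv[i] + rSolv)^2]] <- TRUE
      core[box$flat[d2 <= rv[i]^2]] <- TRUE
    }
  }
  solvent <- !protein
  # dilate the solvent region by rShrink via FFT convolution with a
  # spherical kernel, then reassign boundary protein voxels
  kernel <- array(0, dims)
  kb <- .voxelBox(c(0, 0, 0), rShrink, frame, dims)
  kernel[kb$flat[rowSums(kb$dcart^2) <= rShrink^2]] <- 1
  conv <- Re(fft(fft(array(as.numeric(solvent), dims)) *
                 fft(kernel), inverse = TRUE)) / ntot
  nearSolvent <- conv > 0.5
  solvent <- solvent | (protein & !core & as.logical(nearSolvent))
  m <- array(solvent, dims)
  new("SolventMask", grid = dims, solvent = m, fraction = mean(solvent))
}

#' Fourier transform of a solvent mask
#'
#' FFT of the binary solvent indicator, restricted to the given Miller set.
#' F_mask(0,0,0) equals solvent fraction times cell volume.
#'
#' @param mask a [SolventMask-class].
#' @param frame the [CrystalFrame-class] the mask was built on.
#' @param miller n x 3 integer matrix.
#' @return complex vector.
#' @export
fMask <- function(mask, frame, miller) {
  miller <- rbind(miller)
  dims <- mask@grid
  Fgrid <- fft(array(as.numeric(mask@solvent), dims), inverse = TRUE) *
    (cellVolume(frame) / prod(dims))
  idx <- 1L + (miller[, 1] %% dims[1]) +
    dims[1] * ((miller[, 2] %% dims[2]) + dims[2] * (miller[, 3] %% dims[3]))
  Fgrid[idx]
}

#' R factor between two amplitude sets
#'
#' sum(||Fa| - |Fb||) / sum(|Fa|).
#' @param fa,fb numeric or complex vectors.
#' @export
amplitudeR <- function(fa, fb) {
  sum(abs(abs(fa) - abs(fb))) / sum(abs(fa))
}
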