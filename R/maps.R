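# Likelihood-weighted maps: sigma-A estimation (Rice/Woolfson), m and D
# coefficients, map-coefficient synthesis (2mFo-DFc and relatives), FFT map
# synthesis with sigma scaling, and real-space map correlation per atom or
# residue.

.logI0 <- function(x) log(besselI(x, 0, expon.scaled = TRUE)) + x
.logCosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

#' Estimate sigma-A, figures of merit and D factors
#'
#' Normalized amplitudes E (epsilon-corrected) are computed per resolution
#' bin for both the observations and the model; per bin, sigma_A maximizes
#' the Rice (acentric) / Woolfson (centric) log-likelihood of |E_obs| given
#' |E_model| by bounded 1-D search on (0, 0.999). Per reflection the figure
#' of merit is m = I1(X)/I0(X) (acentric) or tanh(X/2) (centric) with
#' X = 2 sigmaA Eo Ec / (1 - sigmaA^2), and D = sigmaA *
#' sqrt(<Fo^2>_bin / <Fm^2>_bin). Bins with fewer than 20 reflections are
#' merged with their neighbour.
#'
#' @param fObs,fModelAmp observed and model amplitude vectors.
#' @param set the [ReflectionSet-class] the amplitudes belong to.
#' @param frame a [CrystalFrame-class].
#' @param nBins target number of resolution bins.
#' @return a [SigmaATable-class].
#' @export
estimateSigmaA <- function(fObs, fModelAmp, set, frame, nBins = 10) {
  n <- length(fObs)
  d <- dSpacing(set@miller, frame)
  eps <- set@epsilon
  cen <- set@centric
  nBins <- max(1, min(nBins, floor(n / 20)))
  bins <- .equalCountBins(d, nBins)
  m <- numeric(n); D <- numeric(n)
  binRows <- list()
  for (b in sort(unique(bins))) {
    sel <- bins == b
    eo2 <- fObs[sel]^2 / eps[sel]
    ec2 <- fModelAmp[sel]^2 / eps[sel]
    Eo <- sqrt(eo2 / mean(eo2)); Ec <- sqrt(ec2 / mean(ec2))
    isCen <- cen[sel]
    negLL <- function(sa) {
      om <- 1 - sa^2
      Xa <- 2 * sa * Eo * Ec / om
      lla <- log(2 * Eo / om) - (Eo^2 + sa^2 * Ec^2) / om + .logI0(Xa)
      llc <- 0.5 * log(2 / (pi * om)) -
        (Eo^2 + sa^2 * Ec^2) / (2 * om) + .logCosh(Xa / 2)
      -sum(ifelse(isCen, llc, lla))
    }
    sa <- optimize(negLL, c(1e-4, 0.999))$minimum
    X <- 2 * sa * Eo * Ec / (1 - sa^2)
    mi <- ifelse(isCen, tanh(X / 2),
                 besselI(X, 1, expon.scaled = TRUE) /
                   besselI(X, 0, expon.scaled = TRUE))
    Db <- sa * sqrt(mean(fObs[sel]^2) / mean(fModelAmp[sel]^2))
    m[sel] <- mi
    D[sel] <- Db
    binRows[[length(binRows) + 1L]] <-
      data.frame(dMax = max(d[sel]), dMin = min(d[sel]), n = sum(sel),
                 sigmaA = sa, D = Db)
  }
  new("SigmaATable", bins = do.call(rbind, binRows), m = m, D = D,
      bin = as.integer(bins))
}

#' Map coefficients
#'
#' Builds complex Fourier coefficients for the requested map type, with
#' phases from the model structure factors:
#' \itemize{
#'   \item "2mfo-dfc": (2 m |Fo| - D |Fm|) exp(i phi_model)
#'   \item "mfo-dfc":  (m |Fo| - D |Fm|) exp(i phi_model)
#'   \item "3fo-2fc":  (3 |Fo| - 2 |Fm|) exp(i phi_model)
#'   \item "fc":       the model structure factors themselves
#'   \item "anom":     (F+ - F-)/2 with a 90-degree phase shift
#' }
#' With `fillMissing`, indices present in `fullMiller` but absent from the
#' observations receive D |Fm| exp(i phi) (the missing-Fobs replacement).
#'
#' @param type map type string.
#' @param set a [ReflectionSet-class] of observed amplitudes.
#' @param fModelC complex model structure factors matching `set`.
#' @param sigmaa a [SigmaATable-class] matching `set` (not needed for
#'   "3fo-2fc"/"fc").
#' @param frame a [CrystalFrame-class].
#' @param fillMissing replace missing observations by D Fc.
#' @param fullMiller,fModelFullC the complete index set and its model
#'   structure factors (required for `fillMissing`).
#' @return list(miller, coeff) of map coefficients.
#' @export
mapCoefficients <- function(type = c("2mfo-dfc", "mfo-dfc", "3fo-2fc", "fc",
                                     "anom"),
                            set, fModelC, sigmaa = NULL, frame,
                            fillMissing = FALSE, fullMiller = NULL,
                            fModelFullC = NULL) {
  type <- match.arg(type)
  fo <- set@value
  fm <- Mod(fModelC)
  phase <- ifelse(fm > 0, fModelC / fm, complex(real = 1))
  if (type == "anom") {
    if (!set@anomalous)
      stop("anomalous difference map requires Friedel pairs (anomalous set)")
    mateCan <- mapToAsu(-set@miller, frame, anomalous = TRUE)$miller
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    idx <- match(key(mateCan), key(set@miller))
    ok <- !is.na(idx) & seq_along(idx) < idx   # one entry per pair
    if (!any(ok)) stop("no Friedel pairs found in the anomalous set")
    dano <- (fo[ok] - fo[idx[ok]]) / 2
    coeff <- dano * phase[ok] * complex(imaginary = 1)
    return(list(miller = set@miller[ok, , drop = FALSE], coeff = coeff))
  }
  amp <- switch(type,
    "2mfo-dfc" = 2 * sigmaa@m * fo - sigmaa@D * fm,
    "mfo-dfc" = sigmaa@m * fo - sigmaa@D * fm,
    "3fo-2fc" = 3 * fo - 2 * fm,
    "fc" = fm)
  miller <- set@miller
  coeff <- amp * phase
  if (fillMissing) {
    if (is.null(fullMiller) || is.null(fModelFullC))
      stop("fillMissing requires fullMiller and fModelFullC")
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    missing <- !(key(fullMiller) %in% key(miller))
    if (any(missing)) {
      hMiss <- fullMiller[missing, , drop = FALSE]
      dMiss <- dSpacing(hMiss, frame)
      # D of the containing bin (nearest by resolution)
      bins <- sigmaa@bins
      mid <- (bins$dMax + bins$dMin) / 2
      Dm <- bins$D[vapply(dMiss, function(x) which.min(abs(mid - x)),
                          integer(1))]
      fcMiss <- fModelFullC[missing]
      fill <- Dm * fcMiss   # D * Fc with the model phase
      miller <- rbind(miller, hMiss)
      coeff <- c(coeff, fill)
    }
  }
  list(miller = miller, coeff = coeff)
}

#' Synthesize a real-space map from coefficients
#'
#' Coefficients are expanded to the full sphere by the space-group operators
#' (F(t(R) h) = F(h) exp(-2 pi i h.t)) and Friedel symmetry, placed on a
#' unit-cell grid and inverse-Fourier-transformed; the map is sigma-scaled
#' (mean 0, standard deviation 1). All-zero coefficients are an error.
#'
#' @param coeffs list(miller, coeff) as from [mapCoefficients()].
#' @param frame a [CrystalFrame-class].
#' @param dMin resolution defining the grid (spacing dMin/4), or explicit
#'   `dims`.
#' @param dims optional integer(3) grid dimensions.
#' @return a [RealSpaceMap-class].
#' @export
synthesizeMap <- function(coeffs, frame, dMin = NULL, dims = NULL) {
  if (all(Mod(coeffs$coeff) == 0))
    stop("all map coefficients are zero: cannot sigma-scale")
  miller <- rbind(coeffs$miller)
  if (is.null(dims)) {
    if (is.null(dMin)) dMin <- min(dSpacing(miller, frame))
    dims <- .gridDims(frame, dMin, 4)
  }
  dims <- as.integer(dims)
  grid <- array(0 + 0i, dims)
  place <- function(h, F) {
    idx <- 1L + (h[, 1] %% dims[1]) +
      dims[1] * ((h[, 2] %% dims[2]) + dims[2] * (h[, 3] %% dims[3]))
    grid[idx] <<- F
  }
  for (op in frame@symops) {
    hop <- miller %*% op$R
    Fop <- coeffs$coeff * exp(-2i * pi * as.numeric(miller %*% op$t))
    place(hop, Fop)
    place(-hop, Conj(Fop))
  }
  vals <- Re(fft(grid)) / cellVolume(frame)
  vals <- vals - mean(vals)
  sdv <- sd(as.numeric(vals))
  if (sdv == 0) stop("flat map: cannot sigma-scale")
  new("RealSpaceMap", grid = dims, values = vals / sdv, frame = frame)
}

#' Trilinear interpolation of map values
#'
#' @param map a [RealSpaceMap-class].
#' @param xyz n x 3 Cartesian coordinates.
#' @return numeric vector of sigma-scaled density values.
#' @export
interpolateMap <- function(map, xyz) {
  dims <- map@grid
  xf <- cartToFrac(rbind(xyz), map@frame) %% 1
  g <- xf * rep(dims, each = nrow(rbind(xyz)))
  i0 <- floor(g); fr <- g - i0
  out <- numeric(nrow(g))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ii <- cbind((i0[, 1] + dx) %% dims[1], (i0[, 2] + dy) %% dims[2],
                (i0[, 3] + dz) %% dims[3])
    out <- out + w * map@values[1L + ii[, 1] +
                                dims[1] * (ii[, 2] + dims[2] * ii[, 3])]
  }
  out
}

#' Real-space map correlation per atom or residue
#'
#' Pearson correlation between two maps over the voxels within `radius`
#' (default 2.0 Angstrom) of each atom site (symmetry-unique copy), or over
#' the union of atom spheres per residue. Sigma-scaled density values of
#' both maps at the atom centres (trilinear interpolation) accompany each
#' correlation. Units with fewer than 10 voxels get NA with a warning.
#'
#' @param mapA,mapB [RealSpaceMap-class] objects on the same grid.
#' @param ensemble a [ModelEnsemble-class] (first model is used).
#' @param granularity "atom" or "residue".
#' @param radius sphere radius, Angstrom.
#' @return data.frame: chain, resseq, name (atom level), cc, densA, densB,
#'   nVoxels.
#' @export
realSpaceCC <- function(mapA, mapB, ensemble,
                        granularity = c("atom", "residue"), radius = 2.0) {
  granularity <- match.arg(granularity)
  if (!all(mapA@grid == mapB@grid)) stop("maps must share one grid")
  frame <- mapA@frame
  dims <- mapA@grid
  tab <- ensemble@models[[1]]
  xf <- cartToFrac(as.matrix(tab[, c("x", "y", "z")]), frame) %% 1
  vox <- lapply(seq_len(nrow(tab)), function(i) {
    box <- .voxelBox(xf[i, ], radius, frame, dims)
    unique(box$flat[rowSums(box$dcart^2) <= radius^2])
  })
  dens <- cbind(interpolateMap(mapA, as.matrix(tab[, c("x", "y", "z")])),
                interpolateMap(mapB, as.matrix(tab[, c("x", "y", "z")])))
  ccOf <- function(flat) {
    if (length(flat) < 10) return(NA_real_)
    suppressWarnings(cor(mapA@values[flat], mapB@values[flat]))
  }
  if (granularity == "atom") {
    cc <- vapply(vox, ccOf, numeric(1))
    if (anyNA(cc)) warning("atoms with fewer than 10 voxels: CC set to NA")
    data.frame(chain = tab$chain, resseq = tab$resseq, name = tab$name,
               cc = cc, densA = dens[, 1], densB = dens[, 2],
               nVoxels = lengths(vox))
  } else {
    key <- paste(tab$chain, tab$resseq)
    res <- do.call(rbind, lapply(unique(key), function(k) {
      sel <- key == k
      flat <- unique(unlist(vox[sel]))
      data.frame(chain = tab$chain[sel][1], resseq = tab$resseq[sel][1],
                 name = NA_character_, cc = ccOf(flat),
                 densA = mean(dens[sel, 1]), densB = mean(dens[sel, 2]),
                 nVoxels = length(flat))
    }))
    res
  }
}
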