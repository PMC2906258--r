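# Synthetic fixtures: toy crystals and simulated observations with known
# ground truth for every pathology the audits catalogue.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

.defaultCell <- function(n, spacegroup, volPerAtom = 30) {
  nOps <- length(spaceGroupOps(spacegroup))
  V <- n * nOps * volPerAtom
  sg <- .normalizeSgSymbol(spacegroup)
  if (grepl("^(P4|I4)", sg)) {
    a <- (V / 1.1)^(1 / 3); c(a, a, 1.1 * a, 90, 90, 90)
  } else if (grepl("^(P3|P6|R3)", sg)) {
    a <- (V / (1.1 * sin(2 * pi / 3)))^(1 / 3)
    c(a, a, 1.1 * a, 90, 90, 120)
  } else if (grepl("^(P23|I23|P213)", sg)) {
    a <- V^(1 / 3); c(a, a, a, 90, 90, 90)
  } else if (grepl("^(P2|P21$|C2)", sg)) {
    a <- (V / (1.05 * 0.93 * sin(97 * pi / 180)))^(1 / 3)
    c(a, 1.05 * a, 0.93 * a, 90, 97, 90)
  } else if (sg %in% c("P1", "P-1")) {
    a <- V^(1 / 3); c(a, 1.04 * a, 0.96 * a, 90, 90, 90)
  } else {
    a <- (V / (1.08 * 0.94))^(1 / 3); c(a, 1.08 * a, 0.94 * a, 90, 90, 90)
  }
}

#' Generate a toy crystal
#'
#' Heavy atoms (C/N/O/S mixture) are placed uniformly inside a compact
#' sub-box of the asymmetric unit — emulating an ordered molecule surrounded
#' by bulk solvent (about 40% protein volume after symmetry expansion) —
#' with a minimum separation of 1.2 Angstrom against all symmetry images; an
#' optional fraction of H atoms is attached 1.0 Angstrom from randomly
#' chosen parents. Output is deterministic under the seed.
#'
#' @param nAtoms number of heavy atoms.
#' @param spacegroup Hermann-Mauguin symbol from the built-in table.
#' @param cell numeric(6), or NULL for a protein-density default (18
#'   Angstrom^3 per atom).
#' @param bRange isotropic B range, Angstrom^2.
#' @param hFraction H atoms added as a fraction of nAtoms.
#' @param seed RNG seed.
#' @return a [ModelEnsemble-class].
#' @export
makeToyCrystal <- function(nAtoms = 150, spacegroup = "P21", cell = NULL,
                           bRange = c(10, 30), hFraction = 0, seed = 1) {
  if (is.null(cell)) cell <- .defaultCell(nAtoms, spacegroup)
  frame <- makeCrystalFrame(cell, spacegroup)
  .withSeed(seed, {
    els <- sample(c("C", "N", "O", "S"), nAtoms, replace = TRUE,
                  prob = c(0.70, 0.15, 0.13, 0.02))
    placedFrac <- matrix(0, 0, 3)
    minSep <- 1.2
    # compact blob: one ASU copy occupies proteinFraction/nOps of the cell
    proteinFraction <- 0.4
    width <- min(0.9, (proteinFraction / length(frame@symops))^(1 / 3))
    lo <- rep(0.03, 3)
    tries <- 0
    while (nrow(placedFrac) < nAtoms) {
      cand <- lo + runif(3) * width
      tries <- tries + 1
      if (tries > 200 * nAtoms)
        stop("cannot place ", nAtoms, " atoms at 1.2 A separation; cell too small")
      ok <- TRUE
      test <- rbind(placedFrac, cand)
      for (op in frame@symops) {
        img <- (test %*% t(op$R) + rep(op$t, each = nrow(test))) %% 1
        dfr <- img - rep(cand, each = nrow(img))
        dfr <- dfr - round(dfr)
        dc <- dfr %*% t(frame@orth)
        d <- sqrt(rowSums(dc^2))
        d <- d[d > 1e-6]  # the candidate maps to itself under identity
        if (length(d) && min(d) < minSep) { ok <- FALSE; break }
      }
      if (ok) placedFrac <- rbind(placedFrac, cand)
    }
    xyz <- placedFrac %*% t(frame@orth)
    n <- nAtoms
    tab <- data.frame(
      serial = 1:n,
      name = paste0(els, ((1:n - 1) %% 4) + 1),
      altloc = " ", resname = "UNK", chain = "A",
      resseq = ceiling((1:n) / 4), icode = " ",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = runif(n, bRange[1], bRange[2]),
      element = els, het = FALSE, stringsAsFactors = FALSE)
    tab$u11 <- tab$u22 <- tab$u33 <- tab$u12 <- tab$u13 <- tab$u23 <- NA_real_
    tab$scatter <- tab$element
    nH <- round(hFraction * nAtoms)
    if (nH > 0) {
      parents <- sample(n, nH)
      dirs <- matrix(rnorm(3 * nH), nH, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      hTab <- tab[parents, ]
      hTab$serial <- n + seq_len(nH)
      hTab$name <- paste0("H", ((seq_len(nH) - 1) %% 4) + 1)
      hTab$element <- "H"; hTab$scatter <- "H"
      hTab[, c("x", "y", "z")] <- tab[parents, c("x", "y", "z")] + dirs
      tab <- rbind(tab, hTab)
    }
    new("ModelEnsemble", models = list(tab), frame = frame,
        tlsGroups = list(), tlsDefects = .emptyTlsDefects(),
        header = list(reportedRWork = NA_real_, reportedRFree = NA_real_,
                      resLimits = c(NA_real_, NA_real_),
                      sigmaCutoff = NA_real_, reportedWilsonB = NA_real_))
  })
}

#' Ground-truth parameters for a simulation
#'
#' @param kSol,bSol flat bulk-solvent parameters.
#' @param uCryst Cartesian anisotropic scale tensor (3x3, Angstrom^2).
#' @param kOverall,bOverall overall scale.
#' @param twinLaw optional 3x3 integer matrix; `twinFraction` alpha.
#' @param noise fractional Gaussian amplitude noise.
#' @param freeFraction size of the test set.
#' @param mode "xray" or "neutron".
#' @param seed RNG seed for noise and free flags.
#' @return list of class "groundTruth".
#' @export
groundTruth <- function(kSol = 0.35, bSol = 46, uCryst = matrix(0, 3, 3),
                        kOverall = 1, bOverall = 0, twinLaw = NULL,
                        twinFraction = 0, noise = 0.03, freeFraction = 0.05,
                        mode = "xray", seed = 1) {
  structure(list(kSol = kSol, bSol = bSol, uCryst = uCryst,
                 kOverall = kOverall, bOverall = bOverall, twinLaw = twinLaw,
                 twinFraction = twinFraction, noise = noise,
                 freeFraction = freeFraction, mode = mode, seed = seed),
            class = "groundTruth")
}

#' Simulate observed amplitudes from a model and ground truth
#'
#' F_obs is built through the production F_model path (or, with
#' `independent = TRUE`, a literal from-scratch transcription of the model
#' equation, for oracle independence): bulk-solvent-corrected scaled
#' amplitudes, optional twin mixing of intensities, Gaussian noise with
#' sigma = noise * |F|, and a seeded 5% free set.
#'
#' @param ensemble a [ModelEnsemble-class] carrying the *true* ADPs.
#' @param truth a [groundTruth()] list.
#' @param dMin resolution limit, Angstrom.
#' @param independent use the slow independent re-derivation.
#' @return a [ReflectionSet-class] with attribute "truth".
#' @export
simulateFobs <- function(ensemble, truth, dMin, independent = FALSE) {
  frame <- ensemble@frame
  miller <- millerSet(frame, dMin)
  if (dMin > 5 && nrow(miller) < 30)
    stop("resolution too coarse: fewer than 30 reflections")
  fC <- if (independent || nrow(miller) * nrow(ensemble@models[[1]]) < 2e5)
    fcalcDirect(ensemble, miller, truth$mode)
  else fcalcFft(ensemble, miller, dMin, truth$mode)
  scale <- .scaleModel(kOverall = truth$kOverall, bOverall = truth$bOverall,
                       uCryst = truth$uCryst, kSol = truth$kSol,
                       bSol = truth$bSol)
  fMv <- if (truth$kSol > 0) {
    mask <- solventMask(ensemble, dMin = dMin)
    fMask(mask, frame, miller)
  } else complex(nrow(miller))
  Fm <- if (independent) {
    s <- .recipVectors(miller, frame); s2 <- rowSums(s * s)
    truth$kOverall * exp(-truth$bOverall * s2 / 4) *
      exp(-2 * pi^2 * rowSums((s %*% truth$uCryst) * s)) *
      Mod(fC + truth$kSol * exp(-truth$bSol * s2 / 4) * fMv)
  } else fModel(scale, fC, fMv, miller, frame)
  if (!is.null(truth$twinLaw) && truth$twinFraction > 0) {
    hT <- miller %*% truth$twinLaw
    can <- mapToAsu(hT, frame)$miller
    idx <- match(paste(can[, 1], can[, 2], can[, 3]),
                 paste(miller[, 1], miller[, 2], miller[, 3]))
    mate <- ifelse(is.na(idx), seq_along(Fm), idx)
    Fm <- sqrt((1 - truth$twinFraction) * Fm^2 +
               truth$twinFraction * Fm[mate]^2)
  }
  .withSeed(truth$seed, {
    sig <- truth$noise * Fm
    fObs <- abs(Fm + rnorm(length(Fm)) * sig)
    free <- runif(length(Fm)) < truth$freeFraction
    set <- makeReflectionSet(miller, fObs, sig, frame, kind = "amplitude",
                             free = free)
    attr(set, "truth") <- truth
    set
  })
}

#' Apply one documented corruption to a fixture
#'
#' Modes on a [ModelEnsemble-class]: "strip_h", "zero_h_adp" (H B factors set
#' to 0), "non_pd_adp" (make the U of `params$serials` non-positive-definite),
#' "negative_occupancy", "drop_anisou", "strip_waters",
#' "multi_model_occupancy" (replicate into `params$nModels` models at
#' occupancy `params$occ`). Modes on a [ReflectionSet-class]:
#' "relabel_intensity" (square the amplitudes but keep the amplitude label).
#'
#' @param obj ensemble or reflection set.
#' @param mode corruption name.
#' @param params mode parameters.
#' @return the corrupted object, with attribute "corruption" describing it.
#' @export
degrade <- function(obj, mode, params = list()) {
  out <- switch(mode,
    strip_h = stripHydrogens(obj),
    zero_h_adp = {
      obj@models <- lapply(obj@models, function(m) {
        m$b[m$element %in% c("H", "D")] <- 0
        m
      })
      obj
    },
    non_pd_adp = {
      serials <- params$serials
      if (is.null(serials)) serials <- obj@models[[1]]$serial[1]
      obj@models <- lapply(obj@models, function(m) {
        sel <- m$serial %in% serials
        m[sel, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
          rep(c(0.01, 0.01, -0.01, 0, 0, 0), each = sum(sel))
        m
      })
      obj
    },
    negative_occupancy = {
      serials <- params$serials
      if (is.null(serials)) serials <- obj@models[[1]]$serial[1]
      obj@models <- lapply(obj@models, function(m) {
        m$occ[m$serial %in% serials] <- -abs(params$occ %||% 0.5)
        m
      })
      obj
    },
    drop_anisou = {
      obj@models <- lapply(obj@models, function(m) {
        m[, c("u11", "u22", "u33", "u12", "u13", "u23")] <- NA_real_
        m
      })
      obj
    },
    strip_waters = {
      obj@models <- lapply(obj@models, function(m)
        m[m$resname != "HOH", , drop = FALSE])
      obj
    },
    multi_model_occupancy = {
      nM <- params$nModels %||% 16
      occ <- params$occ %||% 0.06
      m1 <- obj@models[[1]]
      m1$occ <- occ
      obj@models <- rep(list(m1), nM)
      obj
    },
    relabel_intensity = {
      obj@value <- obj@value^2
      obj@sigma <- 2 * obj@value^0.5 * obj@sigma
      obj
    },
    stop("unknown degradation mode: ", mode))
  attr(out, "corruption") <- c(list(mode = mode), params)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fixture to disk: PDB + SHELX HKL + JSON manifest
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param set a [ReflectionSet-class] (free flags written in the I4 field).
#' @param dir output directory (created).
#' @param name fixture base name.
#' @return the directory path, invisibly.
#' @export
writeFixture <- function(ensemble, set, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePdb(ensemble, file.path(dir, paste0(name, ".pdb")))
  writeShelxHkl(set, file.path(dir, paste0(name, ".hkl")))
  truth <- attr(set, "truth")
  if (!is.null(truth)) {
    truth$uCryst <- as.numeric(truth$uCryst)
    if (!is.null(truth$twinLaw)) truth$twinLaw <- as.integer(truth$twinLaw)
    jsonlite::write_json(unclass(truth),
                         file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(dir)
}

#' Write reflections in SHELX HKL format (3I4,2F8,I4)
#'
#' Amplitudes are rescaled when needed to fit the F8.2 field; free-set
#' reflections carry 1 in the trailing I4 flag field. A 0 0 0 terminator row
#' closes the file.
#'
#' @param set a [ReflectionSet-class].
#' @param path output path.
#' @export
writeShelxHkl <- function(set, path) {
  v <- set@value; s <- set@sigma
  s[is.na(s)] <- 0
  mx <- max(v, s)
  if (mx > 9999.99) { f <- 9999.99 / mx; v <- v * f; s <- s * f }
  free <- if (length(set@free)) as.integer(set@free) else
    integer(length(v))
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f%4d",
                   set@miller[, 1], set@miller[, 2], set@miller[, 3],
                   v, s, free)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
}
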