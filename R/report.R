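# Pipeline orchestration and the four-section plain-text report with its
# machine-readable JSON twin.

.fmtNA <- function(x, fmt = "%.4f") {
  if (is.null(x) || length(x) == 0 || is.na(x)) "n.a." else sprintf(fmt, x)
}

.fitToList <- function(fit) {
  if (is.null(fit)) return(NULL)
  sc <- fit@scale
  out <- list(rWork = fit@rWork, rFree = fit@rFree, nWork = fit@nWork,
              nFree = fit@nFree, nOutliers = fit@nOutliers,
              kOverall = sc@kOverall, bOverall = sc@bOverall,
              kSol = sc@kSol, bSol = sc@bSol,
              uCryst = as.numeric(sc@uCryst),
              adpConvention = fit@adpConvention,
              cutoffVariant = fit@cutoffVariant)
  if (!is.null(fit@twin))
    out$twin <- list(law = as.integer(fit@twin@law),
                     fraction = fit@twin@fraction,
                     untwinnedRWork = attr(fit, "untwinnedR"))
  out
}

#' Run the full model-vs-data pipeline
#'
#' Reads the model and reflection files, detects the data kind, merges to
#' the asymmetric unit, flags Wilson outliers, computes data statistics
#' (completeness shells, Wilson B), audits the model, fits the bulk-solvent
#' and scale model with twin-law and ADP-convention resolution, recomputes
#' R under the header cutoffs, and optionally writes map coefficients and
#' real-space correlations.
#'
#' @param modelPaths character vector of PDB paths.
#' @param dataPath reflection data path.
#' @param dataKind "auto", "amplitude" or "intensity".
#' @param format reflection file format (see [readReflections()]).
#' @param freePath optional separate free-flag file (same formats; the flag
#'   is the last numeric column).
#' @param scattering "xray" or "neutron".
#' @param method structure-factor path, "fft" or "direct".
#' @param twin "auto", "none", or a 3x3 law matrix.
#' @param cc "auto", "atom", "residue" or "none" (auto: per atom when
#'   d_min < 2 Angstrom, else per residue).
#' @param mapType optional map coefficient type to produce
#'   (see [mapCoefficients()]); written to `mapPath` when given.
#' @param mapPath output path for map coefficients (h k l amp phase text).
#' @param nShells completeness shells.
#' @return list of class "mvdReport".
#' @export
runModelVsData <- function(modelPaths, dataPath, dataKind = "auto",
                           format = "auto", freePath = NULL,
                           scattering = "xray", method = "fft",
                           twin = "auto", cc = "none", mapType = NULL,
                           mapPath = NULL, nShells = 10) {
  ensemble <- readPdb(modelPaths)
  frame <- ensemble@frame
  raw <- readReflections(dataPath, format)
  guess <- guessDataKind(raw, frame, declared = if (dataKind == "auto")
    "amplitude" else dataKind)
  kind <- if (dataKind == "auto") guess$kind else dataKind
  raw <- toAmplitudes(raw, kind)
  if (!is.null(freePath)) {
    rawF <- readReflections(freePath, format)
    fv <- if (!is.null(rawF$flag)) rawF$flag else rawF$value
    canD <- mapToAsu(as.matrix(raw[, c("h", "k", "l")]), frame)$miller
    canF <- mapToAsu(as.matrix(rawF[, c("h", "k", "l")]), frame)$miller
    idx <- match(paste(canD[, 1], canD[, 2], canD[, 3]),
                 paste(canF[, 1], canF[, 2], canF[, 3]))
    raw$flag <- fv[idx]
  }
  merged <- mergeToAsu(raw, frame)
  set <- merged$set
  outl <- wilsonOutliers(set, frame)
  tabAll <- do.call(rbind, ensemble@models)
  content <- table(tabAll$element[tabAll$scatter != "X"]) *
    length(frame@symops)
  wb <- tryCatch(wilsonB(set, frame, content),
                 error = function(e) list(B = NA_real_, scale = NA_real_))
  shells <- completenessShells(set, frame, nShells)
  audit <- auditModel(ensemble)
  twinLaws <- if (identical(twin, "auto")) "auto"
              else if (identical(twin, "none")) NULL else list(twin)

  fitAll <- if (length(tlsGroups(ensemble))) {
    conv <- resolveAdpConvention(ensemble, set, method = method,
                                 mode = scattering, twinLaws = twinLaws,
                                 outliers = outl$mask)
    chosen <- if (conv$convention == "total") conv$fits$total
              else conv$fits$residual
    attr(chosen, "adpAlternatives") <- conv$fits
    chosen
  } else {
    fitModelToData(ensemble, set, mode = scattering, method = method,
                   twinLaws = twinLaws, outliers = outl$mask)
  }

  cut <- applyHeaderCutoffs(set, ensemble@header, frame)
  fitCut <- if (cut$variant == "header cutoffs") {
    oc <- wilsonOutliers(cut$set, frame)
    fitModelToData(ensemble, cut$set, mode = scattering, method = method,
                   twinLaws = twinLaws, outliers = oc$mask,
                   adpConvention = fitAll@adpConvention,
                   variant = "header cutoffs")
  } else NULL

  d <- dSpacing(set@miller, frame)
  ccTable <- NULL
  sigmaa <- NULL
  needMaps <- !identical(cc, "none") || !is.null(mapType)
  if (needMaps) {
    fC <- if (method == "direct") fcalcDirect(ensemble, set@miller, scattering)
          else fcalcFft(ensemble, set@miller, min(d), scattering)
    mask <- solventMask(ensemble, dMin = min(d))
    fMv <- fMask(mask, frame, set@miller)
    sc <- fitAll@scale
    fModC <- sc@kOverall * .anisoFactor(sc, .recipVectors(set@miller, frame)) *
      (fC + sc@kSol * exp(-sc@bSol *
         rowSums(.recipVectors(set@miller, frame)^2) / 4) * fMv)
    sigmaa <- estimateSigmaA(set@value, Mod(fModC), set, frame)
    if (!is.null(mapType)) {
      co <- mapCoefficients(mapType, set, fModC, sigmaa, frame)
      if (!is.null(mapPath)) writeMapCoefficients(co, mapPath)
    }
    if (!identical(cc, "none")) {
      gran <- if (cc == "auto") { if (min(d) < 2) "atom" else "residue" }
              else cc
      co2 <- mapCoefficients("2mfo-dfc", set, fModC, sigmaa, frame)
      coF <- mapCoefficients("fc", set, fModC, sigmaa, frame)
      dims <- .gridDims(frame, min(d), 4)
      mapA <- synthesizeMap(co2, frame, dims = dims)
      mapB <- synthesizeMap(coF, frame, dims = dims)
      ccTable <- realSpaceCC(mapA, mapB, ensemble, gran)
    }
  }

  hdr <- ensemble@header
  recomputed <- rWork(fitAll)
  report <- list(
    model = list(
      nModels = nModels(ensemble),
      nAtoms = nrow(ensemble@models[[1]]),
      nHydrogen = sum(ensemble@models[[1]]$element %in% c("H", "D")),
      meanB = mean(tabAll$b),
      nAniso = sum(!is.na(tabAll$u11)),
      nTlsGroups = length(tlsGroups(ensemble)),
      nTlsDefects = nrow(ensemble@tlsDefects),
      audit = audit),
    data = list(
      kind = kind, kindRatio = guess$ratio, kindConfidence = guess$confidence,
      nReflections = nrow(set@miller), nRedundant = merged$nRedundant,
      dMin = min(d), dMax = max(d),
      nFree = if (length(set@free)) sum(set@free) else 0L,
      completeness = shells, wilsonB = wb$B, nOutliers = outl$n,
      twinLawsTested = if (!is.null(attr(fitAll, "twinTable")))
        nrow(attr(fitAll, "twinTable")) else 0L),
    fit = list(
      all = .fitToList(fitAll),
      headerCutoffs = .fitToList(fitCut),
      twinTable = attr(fitAll, "twinTable"),
      adpConvention = fitAll@adpConvention,
      sigmaA = if (!is.null(sigmaa)) sigmaa@bins else NULL,
      cc = ccTable),
    header = list(
      reportedRWork = hdr$reportedRWork %||% NA_real_,
      reportedRFree = hdr$reportedRFree %||% NA_real_,
      recomputedRWork = recomputed,
      rWorkDifference = if (!is.null(hdr$reportedRWork) &&
                            !is.na(hdr$reportedRWork))
        recomputed - hdr$reportedRWork else NA_real_))
  class(report) <- "mvdReport"
  report
}

#' Write map coefficients as plain-column text (h k l amplitude phase)
#'
#' @param coeffs list(miller, coeff).
#' @param path output path.
#' @export
writeMapCoefficients <- function(coeffs, path) {
  amp <- Mod(coeffs$coeff)
  phs <- Arg(coeffs$coeff) * 180 / pi
  writeLines(sprintf("%5d %5d %5d %14.6f %10.4f",
                     coeffs$miller[, 1], coeffs$miller[, 2],
                     coeffs$miller[, 3], amp, phs), path)
}

#' Render a report as plain text
#'
#' Four sections: model, data, model-to-data fit, and the header comparison.
#' Every number shown also appears in the JSON twin ([renderJson()]); absent
#' values are rendered "n.a.".
#'
#' @param report an "mvdReport" from [runModelVsData()].
#' @return character vector of lines.
#' @export
renderText <- function(report) {
  m <- report$model; d <- report$data; f <- report$fit; h <- report$header
  a <- m$audit
  fitLines <- function(fl, label) {
    if (is.null(fl)) return(character(0))
    c(sprintf("  [%s] r_work      : %s", label, .fmtNA(fl$rWork)),
      sprintf("  [%s] r_free      : %s", label, .fmtNA(fl$rFree)),
      sprintf("  [%s] n_work/free : %d / %d", label, fl$nWork, fl$nFree),
      sprintf("  [%s] k_sol/b_sol : %s / %s", label,
              .fmtNA(fl$kSol, "%.3f"), .fmtNA(fl$bSol, "%.1f")),
      if (!is.null(fl$twin))
        sprintf("  [%s] twin alpha  : %.3f (untwinned r_work %s)", label,
                fl$twin$fraction, .fmtNA(fl$twin$untwinnedRWork)))
  }
  lines <- c(
    "MODEL VS DATA",
    "=============",
    "Model:",
    sprintf("  models            : %d", m$nModels),
    sprintf("  atoms per model   : %d (H/D: %d)", m$nAtoms, m$nHydrogen),
    sprintf("  mean B            : %.2f", m$meanB),
    sprintf("  anisotropic atoms : %d", m$nAniso),
    sprintf("  TLS groups        : %d (defects: %d)", m$nTlsGroups,
            m$nTlsDefects),
    sprintf("  audit: non-PD ADP %d | zero ADP %d | occ<0 %d | unknown type %d",
            length(a$nonPositiveDefinite), length(a$zeroAdp),
            length(a$negativeOccupancy), length(a$unknownScatteringType)),
    if (nrow(a$multiModelOccupancy))
      sprintf("  multi-model occupancy: mean per-site total %.3f",
              mean(a$multiModelOccupancy$occTotal)),
    "Data:",
    sprintf("  kind              : %s (moment %s, confidence %s)", d$kind,
            .fmtNA(d$kindRatio, "%.3f"), d$kindConfidence),
    sprintf("  unique reflections: %d (redundant input rows: %d)",
            d$nReflections, d$nRedundant),
    sprintf("  resolution        : %.3f - %.3f", d$dMax, d$dMin),
    sprintf("  free set          : %d", d$nFree),
    sprintf("  completeness      : %s",
            paste(sprintf("%.2f", d$completeness$completeness),
                  collapse = " ")),
    sprintf("  Wilson B          : %s", .fmtNA(d$wilsonB, "%.1f")),
    sprintf("  outliers removed  : %d", d$nOutliers),
    "Fit:",
    sprintf("  ADP convention    : %s", f$adpConvention),
    fitLines(f$all, "all data"),
    fitLines(f$headerCutoffs, "header cutoffs"),
    "Header comparison:",
    sprintf("  reported r_work   : %s", .fmtNA(h$reportedRWork)),
    sprintf("  recomputed r_work : %s", .fmtNA(h$recomputedRWork)),
    sprintf("  difference        : %s", .fmtNA(h$rWorkDifference)))
  unlist(lines)
}

#' @rdname renderText
#' @param path optional output path for the JSON twin.
#' @export
renderJson <- function(report, path = NULL) {
  r <- unclass(report)
  r$model$audit <- lapply(unclass(r$model$audit), function(x)
    if (is.data.frame(x)) x else as.numeric(x))
  js <- jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns", force = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @export
print.mvdReport <- function(x, ...) {
  writeLines(renderText(x))
  invisible(x)
}
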