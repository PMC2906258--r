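# Reflection data: readers for SHELX HKL (3I4,2F8), CNS free-format and
# plain-column text; amplitude/intensity detection; merging to the
# asymmetric unit; free-flag conventions; completeness shells; Wilson B and
# Wilson outlier rejection.

#' Read reflection data
#'
#' Supported formats: SHELX HKL fixed columns (3I4,2F8, terminator row
#' 0 0 0 honoured), CNS-style free text ("INDE h k l FOBS= ... SIGMA= ...",
#' TEST= parsed as a flag column), and plain whitespace-separated columns
#' (h k l value sigma [flag]). With `format = "auto"` the format is sniffed
#' from the line shape.
#'
#' @param path file path (or `text` lines).
#' @param format "auto", "shelx", "cns" or "columns".
#' @param text optional character vector of raw lines.
#' @return data.frame with columns h, k, l, value, sigma and (when present)
#'   flag; attribute "format" records the format used.
#' @export
readReflections <- function(path = NULL, format = c("auto", "shelx", "cns",
                                                    "columns"), text = NULL) {
  format <- match.arg(format)
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty reflection file")
  if (format == "auto") {
    if (any(startsWith(trimws(lines), "INDE"))) format <- "cns"
    else {
      sh <- .tryParseShelx(lines)
      format <- if (!is.null(sh)) "shelx" else "columns"
      if (format == "shelx") return(structure(sh, format = "shelx"))
    }
  }
  out <- switch(format,
    shelx = {
      sh <- .tryParseShelx(lines)
      if (is.null(sh)) stop("not a valid SHELX HKL file")
      sh
    },
    cns = .parseCns(lines),
    columns = .parseColumns(lines))
  structure(out, format = format)
}

.tryParseShelx <- function(lines) {
  if (any(nchar(lines) < 28)) return(NULL)
  h <- suppressWarnings(as.integer(substr(lines, 1, 4)))
  k <- suppressWarnings(as.integer(substr(lines, 5, 8)))
  l <- suppressWarnings(as.integer(substr(lines, 9, 12)))
  v <- suppressWarnings(as.numeric(substr(lines, 13, 20)))
  s <- suppressWarnings(as.numeric(substr(lines, 21, 28)))
  ok <- !(is.na(h) | is.na(k) | is.na(l) | is.na(v) | is.na(s))
  if (!all(ok)) return(NULL)
  fl <- suppressWarnings(as.integer(substr(lines, 29, 32)))
  term <- which(h == 0 & k == 0 & l == 0)
  if (length(term)) {
    keep <- seq_len(min(term) - 1L)
    h <- h[keep]; k <- k[keep]; l <- l[keep]; v <- v[keep]; s <- s[keep]
    fl <- fl[keep]
  }
  if (!length(h)) return(NULL)
  out <- data.frame(h = h, k = k, l = l, value = v, sigma = s)
  if (any(!is.na(fl)) && length(unique(fl[!is.na(fl)])) > 1) out$flag <- fl
  out
}

.parseCns <- function(lines) {
  idx <- which(startsWith(trimws(lines), "INDE"))
  if (!length(idx)) stop("no INDE records found in CNS reflection text")
  rows <- lapply(idx, function(i) {
    ln <- lines[i]
    hkl <- regmatches(ln, regexec(
      "INDE[XE]?\\s+(-?\\d+)\\s+(-?\\d+)\\s+(-?\\d+)", ln))[[1]]
    if (length(hkl) != 4)
      stop("unparseable CNS line ", i, ": ", trimws(ln))
    num <- function(key) {
      m <- regmatches(ln, regexec(paste0(key,
        "\\s*=\\s*(-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)"), ln))[[1]]
      if (length(m) < 2) NA_real_ else as.numeric(m[2])
    }
    v <- num("FOBS"); if (is.na(v)) v <- num("IOBS"); if (is.na(v)) v <- num("F")
    if (is.na(v)) stop("no FOBS/IOBS value on CNS line ", i)
    c(as.numeric(hkl[2:4]), v, num("SIGMA"), num("TEST"))
  })
  m <- do.call(rbind, rows)
  out <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                    l = as.integer(m[, 3]), value = m[, 4], sigma = m[, 5])
  if (!all(is.na(m[, 6]))) out$flag <- m[, 6]
  out
}

.parseColumns <- function(lines) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 4))
    stop("unparseable column line ", which(nt < 4)[1])
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) stop("unparseable column line ", bad[1])
  m <- do.call(rbind, lapply(vals, function(v) v[1:min(6, length(v))]))
  out <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                    l = as.integer(m[, 3]), value = m[, 4],
                    sigma = if (ncol(m) >= 5) m[, 5] else NA_real_)
  if (ncol(m) >= 6) out$flag <- m[, 6]
  out
}

#' Amplitude-or-intensity detection
#'
#' Decides by the acentric Wilson second moment <v^2>/<v>^2 of values
#' normalized per resolution bin: ~4/pi (1.273) for amplitudes, ~2 for
#' intensities (exponential distribution). Any negative value forces
#' "intensity". With fewer than 200 acentric reflections the declared kind
#' is returned with low confidence.
#'
#' @param raw data.frame from [readReflections()].
#' @param frame a [CrystalFrame-class].
#' @param declared fallback kind.
#' @return list(kind, ratio, confidence).
#' @export
guessDataKind <- function(raw, frame, declared = "amplitude") {
  h <- as.matrix(raw[, c("h", "k", "l")])
  v <- raw$value
  if (any(v < 0, na.rm = TRUE))
    return(list(kind = "intensity", ratio = NA_real_, confidence = "high"))
  ce <- centricEpsilon(h, frame)
  acent <- !ce$centric & !is.na(v)
  if (sum(acent) < 200)
    return(list(kind = declared, ratio = NA_real_, confidence = "low"))
  d <- dSpacing(h[acent, , drop = FALSE], frame)
  vv <- v[acent]
  bins <- .equalCountBins(d, max(5, min(20, floor(sum(acent) / 100))))
  ratios <- vapply(split(vv, bins), function(x)
    mean(x^2) / mean(x)^2, numeric(1))
  ratio <- mean(ratios)
  kind <- if (abs(ratio - 4 / pi) < abs(ratio - 2)) "amplitude" else "intensity"
  list(kind = kind, ratio = ratio, confidence = "high")
}

.equalCountBins <- function(d, n) {
  n <- max(1L, as.integer(n))
  r <- rank(-d, ties.method = "first")  # bin 1 = lowest resolution
  as.integer(ceiling(r / (length(d) / n)))
}

#' Convert raw reflection data to amplitudes
#'
#' Intensities become F = sqrt(max(I, 0)) with first-order error propagation
#' sigma_F = sigma_I / (2 F) for F > 0, else sqrt(sigma_I). Amplitudes pass
#' through unchanged.
#'
#' @param raw data.frame (h, k, l, value, sigma).
#' @param kind "amplitude" or "intensity".
#' @return the data.frame with amplitude-scale value/sigma.
#' @export
toAmplitudes <- function(raw, kind) {
  if (kind == "intensity") {
    F <- sqrt(pmax(raw$value, 0))
    sF <- ifelse(F > 0, raw$sigma / (2 * F), sqrt(pmax(raw$sigma, 0)))
    raw$value <- F
    raw$sigma <- sF
  }
  raw
}

#' Merge reflections to the asymmetric unit
#'
#' Maps indices to canonical representatives, averages exact duplicates and
#' reports the number of redundant input rows.
#'
#' @param raw data.frame (h, k, l, value, sigma, optional flag).
#' @param frame a [CrystalFrame-class].
#' @param anomalous keep Friedel mates distinct.
#' @return list(set = [ReflectionSet-class], nRedundant).
#' @export
mergeToAsu <- function(raw, frame, anomalous = FALSE) {
  h <- as.matrix(raw[, c("h", "k", "l")])
  can <- mapToAsu(h, frame, anomalous = anomalous)$miller
  key <- paste(can[, 1], can[, 2], can[, 3])
  first <- !duplicated(key)
  nRed <- sum(!first)
  value <- as.numeric(tapply(raw$value, key, mean))
  sigma <- if (all(is.na(raw$sigma))) rep(NA_real_, sum(first)) else
    as.numeric(tapply(raw$sigma, key, function(x) mean(x, na.rm = TRUE)))
  ukey <- unique(key)
  miller <- can[first, , drop = FALSE]
  # tapply sorts by key; realign to first-occurrence order
  tkey <- sort(unique(key))
  value <- value[match(ukey, tkey)]
  sigma <- sigma[match(ukey, tkey)]
  free <- logical(0)
  if (!is.null(raw$flag)) {
    fl <- tapply(raw$flag, key, function(x) x[1])
    flag <- as.numeric(fl[match(ukey, tkey)])
    ex <- extractFreeFlags(flag)
    free <- if (is.null(ex$mask)) logical(0) else ex$mask
  }
  ce <- centricEpsilon(miller, frame)
  set <- new("ReflectionSet", miller = miller, value = value,
             sigma = sigma, kind = "amplitude", free = free,
             centric = ce$centric, epsilon = as.integer(ce$epsilon),
             anomalous = anomalous)
  list(set = set, nRedundant = nRed)
}

#' Interpret free-R flag conventions
#'
#' A two-valued 0/1 column whose minority fraction is at most 25% marks the
#' minority as the test set; an integer column 0..N with N >= 5 marks value
#' 0 as the test set; a constant column is treated as absent with a warning.
#'
#' @param flag numeric vector of per-reflection flags.
#' @return list(mask = logical or NULL, convention = label).
#' @export
extractFreeFlags <- function(flag) {
  if (is.null(flag) || !length(flag) || all(is.na(flag)))
    return(list(mask = NULL, convention = "absent"))
  u <- sort(unique(flag[!is.na(flag)]))
  if (length(u) == 1) {
    warning("free-flag column is constant; treated as absent")
    return(list(mask = NULL, convention = "absent"))
  }
  if (length(u) == 2 && all(u %in% c(0, 1))) {
    frac1 <- mean(flag == 1, na.rm = TRUE)
    minority <- if (frac1 <= 0.5) 1 else 0
    if (min(frac1, 1 - frac1) <= 0.25)
      return(list(mask = flag == minority, convention = "0/1 minority"))
    return(list(mask = flag == 1, convention = "0/1 ambiguous (taking 1)"))
  }
  if (all(u == round(u)) && max(u) >= 5)
    return(list(mask = flag == 0, convention = "ccp4-style (0 is test)"))
  list(mask = flag == u[1], convention = "smallest value is test")
}

#' Completeness in resolution shells
#'
#' Equal-count shells over the observed reflections; the number of possible
#' reflections per shell is enumerated by brute force over the index box.
#'
#' @param set a [ReflectionSet-class].
#' @param frame a [CrystalFrame-class].
#' @param nShells number of shells.
#' @return data.frame: dMax, dMin, nObs, nPossible, completeness, meanValue.
#' @export
completenessShells <- function(set, frame, nShells = 10) {
  d <- dSpacing(set@miller, frame)
  bins <- .equalCountBins(d, nShells)
  all <- millerSet(frame, dMin = min(d) * 0.999, dMax = max(d) * 1.001,
                   anomalous = set@anomalous)
  dAll <- dSpacing(all, frame)
  # contiguous shell boundaries (midpoints between adjacent shells), so
  # deleted reflections between shells are still counted as possible
  ids <- sort(unique(bins))
  hi <- vapply(ids, function(b) max(d[bins == b]), numeric(1))
  lo <- vapply(ids, function(b) min(d[bins == b]), numeric(1))
  bounds <- c(max(d) + 1e-9,
              if (length(ids) > 1) (lo[-length(ids)] + hi[-1]) / 2,
              min(d) - 1e-9)
  res <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sel <- bins == ids[i]
    nPoss <- sum(dAll <= bounds[i] & dAll > bounds[i + 1])
    data.frame(dMax = hi[i], dMin = lo[i], nObs = sum(sel),
               nPossible = nPoss,
               completeness = min(1, sum(sel) / max(1, nPoss)),
               meanValue = mean(set@value[sel]))
  }))
  res
}

#' Wilson B factor by straight-line Wilson plot
#'
#' ln(<I/epsilon> / sum_i n_i f_i^2(s)) regressed on s^2/2 over shells with
#' d < 4 Angstrom; the slope is -B. Amplitudes are squared into intensities
#' first. Reported as NA when the data do not extend beyond 4 Angstrom.
#'
#' @param set a [ReflectionSet-class].
#' @param frame a [CrystalFrame-class].
#' @param content named integer vector: scattering content of the cell
#'   (atom counts per element).
#' @param nShells shells used for the fit.
#' @return list(B, scale) (both NA when not estimable).
#' @export
wilsonB <- function(set, frame, content, nShells = 10) {
  d <- dSpacing(set@miller, frame)
  I <- if (set@kind == "intensity") set@value else set@value^2
  sel <- d < 4
  if (sum(sel) < 30) return(list(B = NA_real_, scale = NA_real_))
  d <- d[sel]; I <- I[sel] / set@epsilon[sel]
  bins <- .equalCountBins(d, nShells)
  types <- names(content)
  # expected <I> per reflection from the scattering content, averaged per
  # shell alongside the observed mean (avoids the curvature bias of
  # evaluating f^2 only at the shell midpoint)
  fsqAll <- as.numeric(scatteringFactors(types, 1 / d^2, "xray")^2 %*%
                       as.numeric(content))
  sSqHalf <- as.numeric(tapply(1 / d^2, bins, mean)) / 2
  meanI <- as.numeric(tapply(I, bins, mean))
  meanFsq <- as.numeric(tapply(fsqAll, bins, mean))
  n <- as.numeric(table(bins))
  y <- log(meanI / meanFsq)
  fit <- lm(y ~ sSqHalf, weights = n)
  list(B = -unname(coef(fit)[2]), scale = exp(unname(coef(fit)[1])))
}

#' Wilson-statistics outlier detection
#'
#' Values are normalized per resolution shell (E^2 corrected for epsilon);
#' a reflection is flagged when its Wilson tail probability, multiplied by
#' the number of reflections (an expected-extreme-value correction), falls
#' below 0.01. Acentric tail: exp(-E^2); centric: erfc(E/sqrt(2)).
#'
#' @param set a [ReflectionSet-class].
#' @param frame a [CrystalFrame-class].
#' @param nShells shells for normalization.
#' @param cutoff expected-count threshold.
#' @return list(mask = logical outlier flags, n = count).
#' @export
wilsonOutliers <- function(set, frame, nShells = 10, cutoff = 0.01) {
  n <- nrow(set@miller)
  if (!n) return(list(mask = logical(0), n = 0L))
  d <- dSpacing(set@miller, frame)
  I <- if (set@kind == "intensity") set@value else set@value^2
  I <- I / set@epsilon
  bins <- .equalCountBins(d, min(nShells, max(1, floor(n / 30))))
  e2 <- numeric(n)
  for (b in unique(bins)) {
    sel <- bins == b
    e2[sel] <- I[sel] / mean(I[sel])
  }
  p <- ifelse(set@centric, 2 * pnorm(-sqrt(pmax(e2, 0))), exp(-e2))
  mask <- p * n < cutoff
  list(mask = mask, n = sum(mask))
}

#' @importFrom stats pnorm
NULL

#' Construct a ReflectionSet directly
#'
#' @param miller n x 3 integer matrix of (already canonical) indices.
#' @param value,sigma numeric vectors.
#' @param frame a [CrystalFrame-class] (for centric/epsilon).
#' @param kind "amplitude" or "intensity".
#' @param free logical free-set mask (or length 0).
#' @param anomalous logical.
#' @return a [ReflectionSet-class].
#' @export
makeReflectionSet <- function(miller, value, sigma = rep(NA_real_, length(value)),
                              frame, kind = "amplitude", free = logical(0),
                              anomalous = FALSE) {
  ce <- centricEpsilon(miller, frame)
  new("ReflectionSet", miller = miller, value = value, sigma = sigma,
      kind = kind, free = free, centric = ce$centric,
      epsilon = as.integer(ce$epsilon), anomalous = anomalous)
}
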