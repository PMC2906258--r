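#' @import methods
#' @importFrom stats optimize sd cor fft lm coef rnorm runif setNames
#' @importFrom utils head tail
NULL

#' CrystalFrame: unit cell and space-group symmetry
#'
#' Holds the unit-cell parameters and the closed set of symmetry operators.
#' All fractional/Cartesian conversions and reciprocal-space geometry in the
#' package flow through an object of this class.
#'
#' @slot cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @slot spacegroup Hermann-Mauguin symbol, e.g. "P 21 21 21".
#' @slot symops list of operators, each `list(R = 3x3 matrix, t = numeric(3))`
#'   acting on fractional coordinates as `x' = R x + t`.
#' @slot orth 3x3 orthogonalization matrix (PDB convention: a along x,
#'   b in the xy-plane); `frac = solve(orth)`.
#' @export
setClass("CrystalFrame",
  representation(cell = "numeric", spacegroup = "character",
                 symops = "list", orth = "matrix", frac = "matrix"))

setValidity("CrystalFrame", function(object) {
  msgs <- character()
  if (length(object@cell) != 6) msgs <- c(msgs, "cell must have 6 elements")
  else {
    if (any(object@cell[1:3] <= 0)) msgs <- c(msgs, "cell lengths must be > 0")
    if (any(object@cell[4:6] <= 0) || any(object@cell[4:6] >= 180))
      msgs <- c(msgs, "cell angles must lie in (0, 180) degrees")
  }
  if (length(object@symops) < 1) msgs <- c(msgs, "at least one symop required")
  if (!.opsContainIdentity(object@symops))
    msgs <- c(msgs, "identity operator missing from symop set")
  if (!.opsClosed(object@symops))
    msgs <- c(msgs, "symop set not closed under composition")
  if (length(msgs)) msgs else TRUE
})

#' ModelEnsemble: one or more atomic models sharing a crystal frame
#'
#' @slot models list of data.frames, one per MODEL block, with columns
#'   serial, name, altloc, resname, chain, resseq, icode, x, y, z, occ,
#'   b, element, scatter, and u11..u23 (anisotropic U in Angstrom^2, NA when
#'   the atom is isotropic).
#' @slot frame CrystalFrame shared by all models.
#' @slot tlsGroups list of TLSGroup parsed from the header.
#' @slot tlsDefects data.frame of TLS header defects (category a/b/c).
#' @slot header list: reportedRWork, reportedRFree, resLimits, sigmaCutoff,
#'   reportedWilsonB (any may be NA).
#' @export
setClass("ModelEnsemble",
  representation(models = "list", frame = "CrystalFrame",
                 tlsGroups = "list", tlsDefects = "data.frame",
                 header = "list"))

setValidity("ModelEnsemble", function(object) {
  if (length(object@models) < 1) return("at least one model required")
  need <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "x", "y", "z", "occ", "b", "element", "scatter")
  for (m in object@models)
    if (!all(need %in% names(m))) return("model table missing columns")
  TRUE
})

#' TLSGroup: a rigid-body displacement group from a PDB header
#'
#' @slot selection parsed selection: data.frame(chain, from, to).
#' @slot selectionText raw selection text as found in the header.
#' @slot origin numeric(3), Angstrom.
#' @slot T symmetric 3x3, Angstrom^2.
#' @slot L symmetric 3x3, degrees^2 (exactly as written in the file;
#'   conversion to radians happens only when U is reconstructed).
#' @slot S 3x3, Angstrom * degrees.
#' @slot dialect "refmac" or "phenix".
#' @export
setClass("TLSGroup",
  representation(selection = "data.frame", selectionText = "character",
                 origin = "numeric", T = "matrix", L = "matrix",
                 S = "matrix", dialect = "character"))

setValidity("TLSGroup", function(object) {
  if (length(object@origin) != 3) return("origin must have 3 components")
  if (max(abs(object@T - t(object@T))) > 1e-8) return("T must be symmetric")
  if (max(abs(object@L - t(object@L))) > 1e-8) return("L must be symmetric")
  TRUE
})

#' ReflectionSet: unique Miller indices with data values
#'
#' @slot miller integer matrix, n x 3 (canonical after merging).
#' @slot value numeric amplitudes or intensities (arbitrary scale).
#' @slot sigma numeric, same units as value (NA when absent).
#' @slot kind "amplitude" or "intensity".
#' @slot free logical free-R mask (length 0 when absent).
#' @slot centric logical per reflection.
#' @slot epsilon integer multiplicity factor per reflection.
#' @slot anomalous logical flag: Friedel mates kept separate.
#' @export
setClass("ReflectionSet",
  representation(miller = "matrix", value = "numeric", sigma = "numeric",
                 kind = "character", free = "logical", centric = "logical",
                 epsilon = "integer", anomalous = "logical"))

setValidity("ReflectionSet", function(object) {
  n <- nrow(object@miller)
  if (ncol(object@miller) != 3) return("miller must be n x 3")
  if (length(object@value) != n) return("value length != n reflections")
  if (!object@kind %in% c("amplitude", "intensity"))
    return("kind must be amplitude or intensity")
  if (any(!is.na(object@sigma) & object@sigma < 0))
    return("sigmas must be >= 0")
  TRUE
})

#' ScaleModel: bulk-solvent and overall scaling state
#'
#' F_model(h) = kOverall * exp(-bOverall s^2/4) * exp(-2 pi^2 s' uCryst s) *
#'   | F_calc(h) + kSol * exp(-bSol s^2/4) * F_mask(h) |
#' with s the reciprocal vector of h in Cartesian Angstrom^-1.
#'
#' @slot kOverall positive overall scale.
#' @slot bOverall isotropic overall B (Angstrom^2; carries the trace removed
#'   from uCryst).
#' @slot uCryst symmetric zero-trace 3x3 anisotropic scale tensor, Angstrom^2
#'   (Cartesian).
#' @slot kSol unitless bulk-solvent density scale in [0, 1].
#' @slot bSol bulk-solvent smearing B in [0, 400] Angstrom^2.
#' @export
setClass("ScaleModel",
  representation(kOverall = "numeric", bOverall = "numeric",
                 uCryst = "matrix", kSol = "numeric", bSol = "numeric"))

setValidity("ScaleModel", function(object) {
  if (object@kOverall <= 0) return("kOverall must be > 0")
  if (object@bSol < 0) return("bSol must be >= 0")
  if (object@kSol < 0) return("kSol must be >= 0")
  TRUE
})

#' TwinModel: a merohedral twin law and refined fraction
#' @slot law 3x3 integer matrix acting on Miller indices.
#' @slot fraction twin fraction alpha in [0, 0.5].
#' @export
setClass("TwinModel",
  representation(law = "matrix", fraction = "numeric"))

setValidity("TwinModel", function(object) {
  if (object@fraction < 0 || object@fraction > 0.5)
    return("twin fraction must lie in [0, 0.5]")
  if (max(abs(object@law - round(object@law))) > 1e-9)
    return("twin law must be an integer matrix")
  TRUE
})

#' FitResult: R factors and the scaling state that produced them
#' @slot rWork,rFree fractions (rFree NA when no free set).
#' @slot nWork,nFree,nOutliers counts.
#' @slot scale ScaleModel.
#' @slot twin TwinModel or NULL.
#' @slot adpConvention "total" or "residual->total".
#' @slot cutoffVariant "all data" or "header cutoffs".
#' @export
setClass("FitResult",
  representation(rWork = "numeric", rFree = "numeric", nWork = "integer",
                 nFree = "integer", nOutliers = "integer", scale = "ScaleModel",
                 twin = "ANY", adpConvention = "character",
                 cutoffVariant = "character"))

#' SolventMask: binary bulk-solvent indicator on a unit-cell grid
#' @slot grid integer(3) grid dimensions along a, b, c.
#' @slot solvent logical 3D array, TRUE where bulk solvent.
#' @slot fraction solvent volume fraction in [0, 1].
#' @export
setClass("SolventMask",
  representation(grid = "integer", solvent = "array", fraction = "numeric"))

setValidity("SolventMask", function(object) {
  if (object@fraction < 0 || object@fraction > 1)
    return("solvent fraction must lie in [0, 1]")
  TRUE
})

#' SigmaATable: per-bin sigma-A and per-reflection m and D
#' @slot bins data.frame: dMin, dMax, n, sigmaA per resolution bin.
#' @slot m figure of merit per reflection, in [0, 1].
#' @slot D amplitude scale factor per reflection, >= 0.
#' @slot bin bin index per reflection.
#' @export
setClass("SigmaATable",
  representation(bins = "data.frame", m = "numeric", D = "numeric",
                 bin = "integer"))

#' RealSpaceMap: sigma-scaled density on a unit-cell grid
#' @slot grid integer(3).
#' @slot values 3D numeric array (mean 0, sd 1 after sigma scaling).
#' @slot frame CrystalFrame.
#' @export
setClass("RealSpaceMap",
  representation(grid = "integer", values = "array", frame = "CrystalFrame"))

setValidity("RealSpaceMap", function(object) {
  if (abs(mean(object@values)) > 1e-8) return("map not mean-centred")
  if (abs(sd(as.numeric(object@values)) - 1) > 1e-6)
    return("map not sigma-scaled")
  TRUE
})

## ---- show methods ----

setMethod("show", "CrystalFrame", function(object) {
  cat(sprintf("CrystalFrame: %s  a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f  (%d symops)\n",
      object@spacegroup, object@cell[1], object@cell[2], object@cell[3],
      object@cell[4], object@cell[5], object@cell[6], length(object@symops)))
})

setMethod("show", "ModelEnsemble", function(object) {
  ns <- vapply(object@models, nrow, integer(1))
  cat(sprintf("ModelEnsemble: %d model(s), %s atoms; %d TLS group(s), %d TLS defect(s)\n",
      length(object@models), paste(unique(ns), collapse = "/"),
      length(object@tlsGroups), nrow(object@tlsDefects)))
  show(object@frame)
})

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflections (%s)%s\n", nrow(object@miller),
      object@kind,
      if (length(object@free)) sprintf(", %d free", sum(object@free)) else ""))
})

setMethod("show", "ScaleModel", function(object) {
  cat(sprintf("ScaleModel: kOverall=%.4g bOverall=%.2f kSol=%.3f bSol=%.1f  uCryst trace=%.2g\n",
      object@kOverall, object@bOverall, object@kSol, object@bSol,
      sum(diag(object@uCryst))))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s, %s]: R_work=%.4f R_free=%s (n_work=%d n_free=%d, %d outliers)%s\n",
      object@adpConvention, object@cutoffVariant, object@rWork,
      if (is.na(object@rFree)) "n.a." else sprintf("%.4f", object@rFree),
      object@nWork, object@nFree, object@nOutliers,
      if (!is.null(object@twin))
        sprintf("  twin alpha=%.3f", object@twin@fraction) else ""))
})

setMethod("show", "SolventMask", function(object) {
  cat(sprintf("SolventMask: %dx%dx%d grid, solvent fraction %.3f\n",
      object@grid[1], object@grid[2], object@grid[3], object@fraction))
})

## ---- accessors ----

#' Accessors for package classes
#'
#' Small accessor functions in place of direct slot access.
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
cellParameters <- function(x) x@cell

#' @rdname accessors
#' @export
spaceGroup <- function(x) x@spacegroup

#' @rdname accessors
#' @export
symOps <- function(x) x@symops

#' @rdname accessors
#' @export
atomTable <- function(x, model = 1L) x@models[[model]]

#' @rdname accessors
#' @export
nModels <- function(x) length(x@models)

#' @rdname accessors
#' @export
tlsGroups <- function(x) x@tlsGroups

#' @rdname accessors
#' @export
headerInfo <- function(x) x@header

#' @rdname accessors
#' @export
millerIndices <- function(x) x@miller

#' @rdname accessors
#' @export
reflValues <- function(x) x@value

#' @rdname accessors
#' @export
reflSigmas <- function(x) x@sigma

#' @rdname accessors
#' @export
dataKind <- function(x) x@kind

#' @rdname accessors
#' @export
freeFlags <- function(x) x@free

#' @rdname accessors
#' @export
rWork <- function(x) x@rWork

#' @rdname accessors
#' @export
rFree <- function(x) x@rFree

#' @rdname accessors
#' @export
scaleModel <- function(x) x@scale

#' @rdname accessors
#' @export
solventFraction <- function(x) x@fraction

#' @rdname accessors
#' @export
mapValues <- function(x) x@values
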