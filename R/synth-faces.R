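# Procedural face generator. Faces are rendered deterministically from a small
# set of independent generative factors so every downstream stage (VAE
# training, encoding, decoding) can be validated against known ground truth.

.rendererRoles <- c("rotation", "lighting", "background", "face_width",
                    "skin_tone", "smile", "hair_size", "gender_proxy")

#' Default generative factor specification
#'
#' Eight independent factors, each uniform on [-1, 1], covering the semantic
#' roles a disentangled face model is expected to isolate: viewpoint rotation,
#' lighting, background, face width, skin tone, smile, hair size and a gender
#' proxy (brow weight). Identity is defined by the identity-relevant factors
#' (face width, skin tone, hair size, gender proxy); rotation, lighting,
#' background and smile are transformations a face can undergo without
#' changing who it is.
#'
#' @return A data.frame with columns `name`, `identityRelevant`, `lo`, `hi`
#'   and `role` (one of the supported renderer roles).
#' @examples
#' defaultFactorSpec()
#' @export
defaultFactorSpec <- function() {
  data.frame(
    name = .rendererRoles,
    identityRelevant = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    lo = -1, hi = 1,
    role = .rendererRoles,
    stringsAsFactors = FALSE
  )
}

validateFactorSpec <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("name", "identityRelevant", "lo", "hi", "role") %in% names(spec)))
  if (anyDuplicated(spec$name)) stop("factor names must be unique")
  if (any(!is.finite(spec$lo)) || any(!is.finite(spec$hi)) || any(spec$hi <= spec$lo)) {
    stop("factor ranges must be finite and non-degenerate")
  }
  if (!all(spec$role %in% .rendererRoles)) {
    stop("unknown renderer role(s): ",
         paste(setdiff(spec$role, .rendererRoles), collapse = ", "))
  }
  invisible(spec)
}

# Normalized factor value in [0, 1] for a role; 0.5 when the role is absent.
.roleUnit <- function(values, spec, role) {
  i <- match(role, spec$role)
  if (is.na(i)) return(0.5)
  (values[i] - spec$lo[i]) / (spec$hi[i] - spec$lo[i])
}

#' Maximal face-plus-hair mask
#'
#' The pixel region that face and hair can ever occupy under a factor spec
#' (at the widest face and largest hair). The background factor paints only
#' the complement of this mask, so two scenes differing only in background
#' differ only outside it.
#'
#' @param spec Factor specification (see [defaultFactorSpec()]).
#' @param side Image side length in pixels.
#' @return Logical matrix, TRUE inside the maximal face region.
#' @export
faceRegionMask <- function(spec = defaultFactorSpec(), side = 64L) {
  validateFactorSpec(spec)
  g <- .pixelGrid(side)
  faceW <- 0.45 + 0.10   # widest face (face_width unit = 1)
  hairR <- faceW + 0.06 + 0.08   # largest hair
  (g$X^2 / faceW^2 + g$Y^2 / 0.62^2 <= 1) |
    (g$X^2 / hairR^2 + g$Y^2 / 0.72^2 <= 1 & g$Y > 0.05)
}

.pixelGrid <- function(side) {
  cx <- ((seq_len(side) - 0.5) / side) * 2 - 1
  cy <- 1 - ((seq_len(side) - 0.5) / side) * 2
  list(X = matrix(cx, side, side, byrow = TRUE),
       Y = matrix(cy, side, side, byrow = FALSE))
}

# Mouth geometry constants, shared with the documentation below: the mouth is
# an anti-aliased curve of half-thickness .mouthHalf around
#   yc(x) = .mouthY + .mouthCurve * s_smile * ((x - dx) / .mouthSpan)^2
# painted with intensity .mouthBase + .mouthGain * u_smile. The anti-aliasing
# ramp is exactly one pixel tall, so the summed coverage per column is
# independent of where the curve sits; the mean intensity in a fixed mouth box
# is therefore a strictly increasing linear function of the smile factor.
.mouthY <- -0.28
.mouthCurve <- 0.10
.mouthSpan <- 0.22
.mouthHalf <- 0.035
.mouthBase <- 0.15
.mouthGain <- 0.25

#' Render a face image from factor values
#'
#' Deterministically rasterizes a grayscale face from a scene's factor values.
#' Each renderer role changes a visually distinct property: rotation shifts
#' the internal features horizontally, lighting scales a left-right brightness
#' gradient over the skin, background fills the region outside the maximal
#' face mask, face width scales the head ellipse, skin tone sets the base skin
#' intensity, smile bends and brightens the mouth curve, hair size grows the
#' dark cap above the face, and the gender proxy thickens the brow bars.
#'
#' @param values Numeric vector of factor values, one per row of `spec`, each
#'   within its declared range.
#' @param spec Factor specification (see [defaultFactorSpec()]).
#' @param side Image side length in pixels (>= 32).
#' @return Numeric `side` x `side` matrix with values in [0, 1]; row 1 is the
#'   top of the image.
#' @examples
#' img <- renderFace(rep(0, 8), side = 48)
#' dim(img)
#' @export
renderFace <- function(values, spec = defaultFactorSpec(), side = 64L) {
  validateFactorSpec(spec)
  side <- as.integer(side)
  if (side < 32L) stop("side must be at least 32 pixels")
  values <- as.numeric(values)
  if (length(values) != nrow(spec)) {
    stop("expected ", nrow(spec), " factor values, got ", length(values))
  }
  bad <- which(values < spec$lo - 1e-12 | values > spec$hi + 1e-12)
  if (length(bad)) {
    stop(sprintf("factor '%s' value %.4g outside range [%g, %g]",
                 spec$name[bad[1]], values[bad[1]], spec$lo[bad[1]], spec$hi[bad[1]]))
  }

  u <- vapply(.rendererRoles, function(r) .roleUnit(values, spec, r), numeric(1))
  names(u) <- .rendererRoles
  s <- 2 * u - 1   # signed value in [-1, 1]

  g <- .pixelGrid(side)
  X <- g$X; Y <- g$Y
  px <- 2 / side   # pixel height in scene units

  maxMask <- faceRegionMask(spec, side)
  img <- matrix(0.35, side, side)               # neutral backdrop inside mask
  bgVal <- 0.25 + 0.50 * u[["background"]]
  img[!maxMask] <- bgVal

  faceW <- 0.45 + 0.10 * s[["face_width"]]
  hairR <- faceW + 0.06 + 0.08 * u[["hair_size"]]
  hairMask <- (X^2 / hairR^2 + Y^2 / 0.72^2 <= 1) & Y > 0.05
  img[hairMask & maxMask] <- 0.18

  faceMask <- X^2 / faceW^2 + Y^2 / 0.62^2 <= 1
  skinBase <- 0.45 + 0.35 * u[["skin_tone"]]
  skin <- clamp(skinBase * (1 + 0.35 * s[["lighting"]] * X), 0.05, 0.95)
  img[faceMask] <- skin[faceMask]

  dx <- 0.15 * s[["rotation"]]

  # eyes
  for (ex in c(-0.18, 0.18)) {
    eye <- (X - (ex + dx))^2 + (Y - 0.18)^2 <= 0.05^2
    img[eye & faceMask] <- 0.10
  }
  # brows: thickness set by the gender proxy
  browH <- 0.02 + 0.05 * u[["gender_proxy"]]
  for (ex in c(-0.18, 0.18)) {
    brow <- abs(X - (ex + dx)) <= 0.09 & Y >= 0.28 & Y <= 0.28 + browH
    img[brow & faceMask] <- 0.15
  }
  # nose
  nose <- abs(X - 1.1 * dx) <= 0.02 & Y > -0.10 & Y < 0.10
  img[nose & faceMask] <- 0.35

  # mouth: anti-aliased curve with one-pixel ramp (see constants above)
  yc <- .mouthY + .mouthCurve * s[["smile"]] * ((X - dx) / .mouthSpan)^2
  inSpan <- abs(X - dx) <= .mouthSpan
  cov <- clamp((.mouthHalf - abs(Y - yc)) / px + 0.5, 0, 1)
  cov[!inSpan | !faceMask] <- 0
  mouthVal <- .mouthBase + .mouthGain * u[["smile"]]
  img <- img * (1 - cov) + mouthVal * cov

  clamp(img, 0, 1)
}

#' Bounding box of the mouth region
#'
#' Fixed box (independent of the smile value) that contains the mouth curve
#' for any within-range smile; used to probe the smile sweep.
#'
#' @inheritParams renderFace
#' @return List with `rows` and `cols` index vectors into the rendered image.
#' @export
mouthRegion <- function(values, spec = defaultFactorSpec(), side = 64L) {
  i <- match("rotation", spec$role)
  dx <- if (is.na(i)) 0 else 0.15 * (2 * .roleUnit(as.numeric(values), spec, "rotation") - 1)
  xLo <- dx - .mouthSpan; xHi <- dx + .mouthSpan
  yLo <- .mouthY - .mouthCurve - .mouthHalf - 0.05
  yHi <- .mouthY + .mouthCurve + .mouthHalf + 0.05
  cx <- ((seq_len(side) - 0.5) / side) * 2 - 1
  cy <- 1 - ((seq_len(side) - 0.5) / side) * 2
  list(rows = which(cy >= yLo & cy <= yHi), cols = which(cx >= xLo & cx <= xHi))
}

#' Sample a synthetic face dataset
#'
#' Draws factor values independently and uniformly within their declared
#' ranges, renders the faces, and packages them with 20 distinct test faces.
#' Test identities are pairwise distinct in identity-relevant factor space;
#' `testIrrelevantScale` shrinks the spread of the identity-irrelevant factors
#' across test faces towards the range midpoint (1 = full range, 0 = held
#' constant), which defines how strictly "identity" is carried by the relevant
#' factors in a simulation.
#'
#' @param spec Factor specification.
#' @param nTrain Number of training faces (>= 50).
#' @param side Image side length in pixels.
#' @param testRepeats Nominal presentation count per test face, in [40, 60].
#' @param seed Integer seed; the dataset is fully reproducible given it.
#' @param testIrrelevantScale Scale in [0, 1] applied to identity-irrelevant
#'   factor spread across the 20 test faces.
#' @return A \linkS4class{SyntheticFaceSet}.
#' @examples
#' ds <- sampleFaceDataset(nTrain = 50, side = 32, seed = 1)
#' dim(trainFactors(ds))
#' @export
sampleFaceDataset <- function(spec = defaultFactorSpec(), nTrain = 500L,
                              side = 64L, testRepeats = 50L, seed = 1L,
                              testIrrelevantScale = 1) {
  validateFactorSpec(spec)
  if (nTrain < 50L) stop("nTrain must be at least 50")
  stopifnot(testIrrelevantScale >= 0, testIrrelevantScale <= 1)
  k <- nrow(spec)
  withSeed(seed, {
    trainF <- sapply(seq_len(k), function(j) runif(nTrain, spec$lo[j], spec$hi[j]))
    testF <- .sampleTestFactorMatrix(spec, 20L, testIrrelevantScale)
    colnames(trainF) <- spec$name
    trainImgs <- array(0, c(nTrain, side, side))
    for (i in seq_len(nTrain)) trainImgs[i, , ] <- renderFace(trainF[i, ], spec, side)
    testImgs <- array(0, c(20L, side, side))
    for (i in 1:20) testImgs[i, , ] <- renderFace(testF[i, ], spec, side)
    new("SyntheticFaceSet",
        spec = spec, trainImages = trainImgs, trainFactors = trainF,
        testImages = testImgs, testFactors = testF,
        testRepeats = as.integer(testRepeats), seed = as.integer(seed))
  })
}

# Draws nTest factor rows; identity-relevant factors span their full range,
# identity-irrelevant factors are shrunk towards a shared anchor value drawn
# from the middle half of the range (not the midpoint, so collapsed factors
# stay distinguishable from one another). Uses the current RNG stream.
.sampleTestFactorMatrix <- function(spec, nTest, testIrrelevantScale) {
  testF <- sapply(seq_len(nrow(spec)), function(j) {
    x <- runif(nTest, spec$lo[j], spec$hi[j])
    if (!spec$identityRelevant[j]) {
      anchor <- runif(1, spec$lo[j] + 0.25 * (spec$hi[j] - spec$lo[j]),
                      spec$hi[j] - 0.25 * (spec$hi[j] - spec$lo[j]))
      x <- clamp(anchor + testIrrelevantScale * (x - anchor), spec$lo[j], spec$hi[j])
    }
    x
  })
  colnames(testF) <- spec$name
  testF
}

#' Sample test-identity factor values only
#'
#' Factor-level counterpart of [sampleFaceDataset()] for analyses that do not
#' need rendered images: identity-relevant factors are drawn uniformly over
#' their full range, identity-irrelevant factors are shrunk by
#' `testIrrelevantScale` towards a shared per-factor anchor (0 collapses them
#' to identical values across identities).
#'
#' @inheritParams sampleFaceDataset
#' @param nTest Number of test identities.
#' @return nTest x factors matrix.
#' @export
sampleTestFactors <- function(spec = defaultFactorSpec(), nTest = 20L,
                              seed = 1L, testIrrelevantScale = 1) {
  validateFactorSpec(spec)
  stopifnot(testIrrelevantScale >= 0, testIrrelevantScale <= 1)
  withSeed(seed, .sampleTestFactorMatrix(spec, nTest, testIrrelevantScale))
}

#' Flatten an image stack to a matrix
#'
#' @param images Numeric array, n x side x side.
#' @return Matrix n x side^2 (row-major flattening of each image).
#' @export
imagesToMatrix <- function(images) {
  d <- dim(images)
  matrix(images, nrow = d[1])
}

#' Reshape a flat pixel vector back to an image
#'
#' @param x Numeric vector of length side^2.
#' @param side Image side length.
#' @return side x side matrix.
#' @export
vectorToImage <- function(x, side) {
  matrix(x, side, side)
}
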