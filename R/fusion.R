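# Region-energy fusion rule, the full PCNN-NSCT pipeline, and the two
# reference fusers.

#' Region-energy templates
#'
#' `lowpassEnergyTemplate()` is the uniform 3x3 mean `w1 = ones(3,3)/9` used
#' for the low-pass band. `highpassEnergyTemplate()` is the center-dominant
#' normalized template `w2 = [1 2 1; 2 4 2; 1 2 1] / 16` used for the
#' high-pass bands to strengthen the coefficients at the window center.
#'
#' @return A 3x3 non-negative matrix summing to 1.
#' @export
lowpassEnergyTemplate <- function() matrix(1 / 9, 3L, 3L)

#' @rdname lowpassEnergyTemplate
#' @export
highpassEnergyTemplate <- function() {
  matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3L, 3L) / 16
}

#' Template-weighted region energy
#'
#' `E(i,j) = sum_{a,b} template(a,b) * C(i+a, j+b)^2` over the 3x3
#' neighbourhood, with padded borders. In the fusion pipeline `C` is a PCNN
#' firing-count map.
#'
#' @param C Input map (matrix; firing counts are accepted as numeric).
#' @param template 3x3 non-negative weights.
#' @param boundary Padding mode.
#' @return Non-negative energy map of `dim(C)`.
#' @export
regionEnergy <- function(C, template = lowpassEnergyTemplate(),
                         boundary = c("symmetric", "periodic")) {
  if (is.integer(C)) C <- C + 0
  .assertImage(C, "C")
  if (!is.matrix(template) || !all(dim(template) == c(3L, 3L)))
    stop("'template' must be a 3x3 matrix", call. = FALSE)
  conv2d(C^2, template, match.arg(boundary))
}

#' Max-region-energy coefficient selection
#'
#' Picks each fused coefficient from the source whose region energy is
#' strictly larger: `fused = D_A` where `E_A > E_B`, otherwise `D_B` (ties
#' go to B).
#'
#' @param DA,DB Subband coefficients of the two sources.
#' @param EA,EB Region-energy maps of the corresponding firing maps.
#' @return `list(fused = <matrix>, mask = <logical matrix>)`; `TRUE` in the
#'   mask marks coefficients taken from A.
#' @export
selectMaxEnergy <- function(DA, DB, EA, EB) {
  .assertImage(DA, "DA"); .assertImage(DB, "DB")
  .assertImage(EA, "EA"); .assertImage(EB, "EB")
  .assertSameShape(DA, DB, "DA", "DB")
  .assertSameShape(DA, EA, "DA", "EA")
  .assertSameShape(DA, EB, "DA", "EB")
  mask <- EA > EB
  fused <- DB
  fused[mask] <- DA[mask]
  list(fused = fused, mask = mask)
}

#' Construct a fusion configuration
#'
#' @param spec [DecompositionSpec-class]; default 3 levels, directions
#'   `c(2, 2, 3)`.
#' @param bankName Filter-bank preset for [buildFilterBank()].
#' @param pcnn [PCNNParams-class]; default [pcnnParams()].
#' @param lowTemplate,highTemplate 3x3 region-energy templates; defaults
#'   [lowpassEnergyTemplate()] and [highpassEnergyTemplate()].
#' @param boundary `"symmetric"` (default) or `"periodic"` (exactly
#'   shift-equivariant pipeline).
#' @return A [FusionConfig-class] object.
#' @export
fusionConfig <- function(spec = decompositionSpec(), bankName = "maxflat",
                         pcnn = pcnnParams(),
                         lowTemplate = lowpassEnergyTemplate(),
                         highTemplate = highpassEnergyTemplate(),
                         boundary = c("symmetric", "periodic")) {
  new("FusionConfig", spec = spec, bankName = bankName, pcnn = pcnn,
      lowTemplate = lowTemplate, highTemplate = highTemplate,
      lowFeature = "NSML", highFeature = "EOE",
      boundary = match.arg(boundary))
}

# fuse one subband pair: feature -> normalize -> adaptive beta -> PCNN ->
# region energy of the firing maps -> max-energy selection
.fuseBand <- function(a, b, featureFun, template, config, pcnnBoundary) {
  fa <- normalize01(featureFun(a))
  fb <- normalize01(featureFun(b))
  fira <- runPCNN(fa, linkingStrengthMap(fa, config@boundary), config@pcnn,
                  pcnnBoundary)
  firb <- runPCNN(fb, linkingStrengthMap(fb, config@boundary), config@pcnn,
                  pcnnBoundary)
  ea <- regionEnergy(fira, template, config@boundary)
  eb <- regionEnergy(firb, template, config@boundary)
  sel <- selectMaxEnergy(a, b, ea, eb)
  list(fused = sel$fused, mask = sel$mask, firA = fira, firB = firb)
}

#' Fuse a co-registered PET/CT image pair
#'
#' The full pipeline: (1) NSCT-decompose both sources; (2) compute the NSML
#' feature on the low-pass bands and the EOE feature on every directional
#' high-pass band, min-max normalizing each feature map to `[0,1]`; (3) run
#' a simplified PCNN per band, with per-pixel linking strength from
#' [linkingStrengthMap()] of the normalized feature map, to obtain firing
#' maps; (4) fuse each band by max region energy of the firing maps
#' (`lowTemplate` for the low band, `highTemplate` for high bands); (5)
#' invert the NSCT. Deterministic.
#'
#' @param A,B Same-shape finite matrices (conventionally intensities in
#'   `[0,1]`; see [readGrayImage()]).
#' @param config [FusionConfig-class]; default [fusionConfig()].
#' @param keepDecompositions Retain the source and fused decompositions in
#'   the result (default `TRUE`; set `FALSE` to save memory).
#' @return A [FusionResult-class]; extract the image with [fusedImage()].
#' @examples
#' ph <- makePhantomPair(1, size = 64)
#' res <- fusePETCT(ctImage(ph), petImage(ph),
#'                  fusionConfig(spec = decompositionSpec(2, c(2, 2))))
#' dim(fusedImage(res))
#' @export
fusePETCT <- function(A, B, config = fusionConfig(),
                      keepDecompositions = TRUE) {
  .assertImage(A, "A"); .assertImage(B, "B")
  .assertSameShape(A, B)
  validObject(config)
  bank <- buildFilterBank(config@bankName)
  bd <- config@boundary
  pcnnBoundary <- if (bd == "periodic") "periodic" else "zero"
  dA <- nsctForward(A, config@spec, bank, bd)
  dB <- nsctForward(B, config@spec, bank, bd)

  lowFeat <- function(x) nsmlMap(x, 3L, bd)
  highFeat <- function(x) eoeMap(x, boundary = bd)

  lowSel <- .fuseBand(dA@low, dB@low, lowFeat, config@lowTemplate, config,
                      pcnnBoundary)
  levels <- config@spec@levels
  fusedHigh <- vector("list", levels)
  maskHigh <- vector("list", levels)
  firAHigh <- vector("list", levels)
  firBHigh <- vector("list", levels)
  for (k in seq_len(levels)) {
    nb <- length(dA@high[[k]])
    fusedHigh[[k]] <- vector("list", nb)
    maskHigh[[k]] <- vector("list", nb)
    firAHigh[[k]] <- vector("list", nb)
    firBHigh[[k]] <- vector("list", nb)
    for (d in seq_len(nb)) {
      sel <- .fuseBand(dA@high[[k]][[d]], dB@high[[k]][[d]], highFeat,
                       config@highTemplate, config, pcnnBoundary)
      fusedHigh[[k]][[d]] <- sel$fused
      maskHigh[[k]][[d]] <- sel$mask
      firAHigh[[k]][[d]] <- sel$firA
      firBHigh[[k]][[d]] <- sel$firB
    }
  }
  fusedDecomp <- new("SubbandDecomposition", low = lowSel$fused,
                     high = fusedHigh, spec = config@spec,
                     sourceShape = dim(A), boundary = bd)
  fused <- nsctInverse(fusedDecomp, bank)
  new("FusionResult", fused = fused,
      decompositionA = if (keepDecompositions) dA else NULL,
      decompositionB = if (keepDecompositions) dB else NULL,
      fusedDecomposition = if (keepDecompositions) fusedDecomp else NULL,
      selectionMasks = list(low = lowSel$mask, high = maskHigh),
      firingMapsA = list(low = lowSel$firA, high = firAHigh),
      firingMapsB = list(low = lowSel$firB, high = firBHigh),
      config = config)
}

#' DWT maximum-absolute-value fusion baseline
#'
#' Decomposes both images with a separable LeGall 5/3 (biorthogonal 2.2)
#' lifting wavelet under periodic extension, selects each coefficient
#' (approximation and details) by maximum absolute value, and inverts.
#'
#' @param A,B Same-shape matrices with dimensions divisible by
#'   `2^levels`.
#' @param levels Decomposition depth (default 3).
#' @return Fused image matrix.
#' @export
baselineDWTMax <- function(A, B, levels = 3L) {
  .assertImage(A, "A"); .assertImage(B, "B")
  .assertSameShape(A, B)
  wa <- .dwt2(A, levels)
  wb <- .dwt2(B, levels)
  pick <- function(a, b) { out <- b; i <- abs(a) >= abs(b); out[i] <- a[i]; out }
  fused <- list(ll = pick(wa$ll, wb$ll),
                detail = lapply(seq_len(levels), function(k)
                  Map(pick, wa$detail[[k]], wb$detail[[k]])))
  .idwt2(fused)
}

#' NSCT maximum-selection fusion baseline
#'
#' Decomposes both images with the NSCT and takes every coefficient — low-
#' and high-pass alike — from the source with the larger absolute value
#' (ties go to A), then inverts.
#'
#' @param A,B Same-shape matrices.
#' @param config [FusionConfig-class] supplying the decomposition spec,
#'   bank and boundary mode.
#' @return Fused image matrix.
#' @export
baselineNSCTMax <- function(A, B, config = fusionConfig()) {
  .assertImage(A, "A"); .assertImage(B, "B")
  .assertSameShape(A, B)
  bank <- buildFilterBank(config@bankName)
  dA <- nsctForward(A, config@spec, bank, config@boundary)
  dB <- nsctForward(B, config@spec, bank, config@boundary)
  pick <- function(a, b) { out <- b; i <- abs(a) >= abs(b); out[i] <- a[i]; out }
  fused <- new("SubbandDecomposition", low = pick(dA@low, dB@low),
               high = lapply(seq_len(config@spec@levels), function(k)
                 Map(pick, dA@high[[k]], dB@high[[k]])),
               spec = config@spec, sourceShape = dim(A),
               boundary = config@boundary)
  nsctInverse(fused, bank)
}
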