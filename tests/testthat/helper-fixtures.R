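# Shared fixtures, generated in code at test time.

tinySpec <- function(seed = 1L, organs = dualsct:::.phantomOrgans) {
  phantomSpec(gridShape = c(32L, 32L, 8L), spacingMm = c(8, 8, 8),
              headAxesMm = c(80, 95, 30), organs = organs, seed = seed,
              jitterFrac = 0.03)
}

randomVolume <- function(d = c(8, 8, 8), seed = 1, lo = -500, hi = 1500,
                         spacing = c(1, 1, 1)) {
  set.seed(seed)
  VolumeGrid(array(runif(prod(d), lo, hi), d), spacing = spacing)
}

# One cached small triplet, shared across tests that only read it.
.cache <- new.env()
cachedTriplet <- function() {
  if (is.null(.cache$triplet))
    .cache$triplet <- simulateTriplet(phantomSpec(
      gridShape = c(32L, 32L, 8L), spacingMm = c(8, 8, 8),
      headAxesMm = c(80, 95, 30), seed = 11L, jitterFrac = 0.03))
  .cache$triplet
}

# Tiny two-level generator for fast training tests (32x32 slices).
tinyGenerator <- function(inChannels = 1L, seed = 1L, residual = TRUE) {
  buildResUnet(generatorConfig("resunet", inChannels = inChannels,
                               filters = c(4L, 8L), sliceShape = c(32L, 32L),
                               residual = residual),
               seed = seed)
}

tinyDiscriminator <- function(inChannels = 2L, seed = 1L) {
  buildDiscriminator(discriminatorConfig(filters = c(4L, 8L),
                                         inChannels = inChannels), seed = seed)
}
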