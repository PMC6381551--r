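# Small scenes and design tables used across tests.

# Single-nodule scene on a small field of view (fast to render).
smallScene <- function(targetHu = 100, diameterMm = 12) {
  phantomScene(
    nodules = list(noduleSpec(diameterMm, targetHu, c(12.6, 12.6, 10))),
    fieldOfViewMm = c(25.2, 25.2, 20))
}

# Nodule-free scene: homogeneous background for noise measurements.
backgroundScene <- function() {
  phantomScene(nodules = list(), fieldOfViewMm = c(28, 28, 20))
}

# Covariate skeleton of one density stratum: 12 protocols x reps
# repetitions x 2 diameters (the regression design, without features).
strataDesignTable <- function(reps = 10) {
  p <- allProtocols()
  rows <- p[rep(seq_len(nrow(p)), each = reps * 2), ]
  rows$repetition <- rep(rep(seq_len(reps), each = 2), times = nrow(p))
  rows$diameter_mm <- rep(c(10, 12), times = nrow(p) * reps)
  data.frame(thickness_mm = rows$thicknessMm, mas = rows$tubeCurrentMas,
             kernel = rows$reconKernel, repetition = rows$repetition,
             diameter_mm = rows$diameter_mm)
}

# A synthetic feature table: every feature is independent noise plus
# optional injected dummy effects (named list, e.g.
# list(thickness_1.25 = 0.4)).
syntheticFeatureTable <- function(reps = 10, effects = list(),
                                  noiseSd = 0.05, base = 0.3) {
  tab <- strataDesignTable(reps)
  n <- nrow(tab)
  for (f in featureNames()) {
    y <- base + stats::rnorm(n, 0, noiseSd)
    if (!is.null(effects$thickness_2.5))
      y <- y + effects$thickness_2.5 * (tab$thickness_mm == 2.5)
    if (!is.null(effects$thickness_1.25))
      y <- y + effects$thickness_1.25 * (tab$thickness_mm == 1.25)
    if (!is.null(effects$mas_120))
      y <- y + effects$mas_120 * (tab$mas == 120)
    if (!is.null(effects$kernel_standard))
      y <- y + effects$kernel_standard * (tab$kernel == "standard")
    tab[[f]] <- y
  }
  tab$density_hu <- 100
  tab
}
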