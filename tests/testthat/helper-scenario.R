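# Shared fixtures: small synthetic scenarios, built once per test run.

.scenario_cache <- new.env(parent = emptyenv())

## A compact planted scenario used by several test files.
smallScenario <- function(seed = 11, noiseSd = 0.2) {
  key <- paste0("s", seed, "_", noiseSd)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generateScenario(simParams(
      nKinases = 2L, substratesPerKinase = 20L, nDecoyPeptides = 80L,
      nNetworkNodes = 150L, backgroundEdgeProb = 0.01,
      pwmSharpness = 0.05, noiseSd = noiseSd, seed = seed))
  }
  .scenario_cache[[key]]
}

## A MotifModule carrying only protein membership, for network-level tests.
proteinModule <- function(id, proteins, class = "A_inc") {
  new("MotifModule", moduleId = id, classLabel = class, central = "S",
      fixed = data.frame(pos = integer(0), residue = character(0),
                         stringsAsFactors = FALSE),
      peptideIds = character(0), proteinIds = proteins,
      windows = character(0), width = 13L)
}

## Uniform-random windows centered on `central`.
uniformWindows <- function(n, central = "S", width = 13L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    w <- sample(aa, width, replace = TRUE)
    w[(width + 1) %/% 2] <- central
    paste(w, collapse = "")
  }, character(1))
}
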