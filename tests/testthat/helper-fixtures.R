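# shared fixtures built in code

# near-step observer: percept flips deterministically at t50
stepObserver <- function(t50, detThreshold = 2.4) {
  Observer(t50 = t50, scale = 1e-9, detThreshold = detThreshold)
}

# tiny ScalpVolumes on an ng x ng grid with a full mask
toyVolumes <- function(data, ng = 4, nt, meta = data.frame()) {
  new("ScalpVolumes", gridX = seq(-1, 1, length.out = ng),
      gridY = seq(-1, 1, length.out = ng),
      mask = rep(TRUE, ng * ng), times = seq_len(nt) / 1000,
      data = data, meta = meta)
}

# noiseless per-ISI counts from an observer (expected counts, may be
# non-integer; fitLogistic accepts them for self-consistency oracles)
expectedCounts <- function(obs, isis, reps = 20) {
  data.frame(isi = isis, nTwo = reps * psychometricP(isis, obs),
             nTrials = reps)
}

# canonical 10-level design used across tests
defaultDesign <- function() {
  fit <- PsychometricFit(t50 = 40.51, scale = (78.56 - 2.45) / (2 * log(99)))
  lv <- designIsiLevels(fit)
  ISIDesign(lv, allocateTrials(lv))
}
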