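# Example pipeline configuration: a small simulated validation study.
seed: 1
targetStack: 1
band: [115.0, 180.0]
simulation:
  phantom:
    fovMm: 64.0
    spacing: 1.0
    nPhases: 12
    heartRateBpm: 150.0
    contractionFrac: 0.25
  stacks:
    n: 3
    slices: 8
    framesPerSlice: 48
    fovMm: 64.0
    inPlaneMm: 2.0
    thicknessMm: 6.0
    overlapMm: 2.5
  frameInterval: 0.072
  noiseSd: 0.05
  motion:
    dispMm: 5.6
recon:
  spacing: 2.0
  nPhases: 16
  lambda: 0.05
  delta: 0.25
  nSR: 20
  nMC: 3
  sliceIters: 4
  staticSpacing: 2.5
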