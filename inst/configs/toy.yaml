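# Desk-scale configuration: 64x64 phantoms, a slim generator, short
# adversarial schedule. The phantom block states the simulated study
# conditions; the generator/training blocks are sized so a full run fits a
# single CPU.
phantom:
  heightPx: 64
  widthPx: 64
  nLayers: 6
  layerCurvature: 6
  speckleLooks: 2
  contrastScale: 0.45
  motionAmplitudePx: 1.5
  framesPerSequence: 5
  blurSigmaPx: 0.8
  sensorNoiseSd: 0.003
dataset:
  n_lr: 32
  n_hr: 32
generator:
  nResBlocks: 4
  featChannels: 16
  downsampleStride: 4
  upChannels: 8
  flowBackend: builtin
  residualSkip: true
  projDim: 64
training:
  lr: 0.001
  decayAfter: 10
  epochs: 19          # 16 steps/epoch at batch 2 over 32 sequences -> 304 steps
  batchSize: 2
  seqLen: 5
  lambdaGAN: 1
  lambdaContr: 20
  lambdaPerc: 1
  nPatches: 64
  tau: 0.07
  dFilters: 16
  lossFramesPerSeq: 1
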