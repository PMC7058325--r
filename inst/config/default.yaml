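# Desk-scale pipeline defaults (keys mirror pipelineConfig()).
# Every knob the analysis depends on is explicit here.
seed: 1
nPerClass: 8
nSegTrain: 8
workSide: 64
simulator:
  imageSize: 96
  treeDepth: 4
  rootDiameter: 8
  murrayExponent: 3          # classical minimum-work value
  angleMean: 75              # degrees, total opening angle
  angleSd: 12
  asymmetryMean: 0.75        # (min(d1,d2)/max(d1,d2))^2
  asymmetrySd: 0.1
  classEffect: -0.25         # hypertension shift of asymmetryMean
  classEffectAngle: 0        # angle is not blood-pressure-associated
  effectMode: bifurcation    # or: diffuse (uniform caliber shift control)
  caliberShift: -0.18
  backgroundTextureSd: 0.04
  illuminationGradient: 0.25
  vesselContrast: 0.55
  darkVessels: true
  twoEyeProb: 0.4
preprocess:
  gamma: 0.8333333333333334  # 1/1.2
  gammaNorm: 1.0
  claheTiles: 8
  claheClip: 0.01
  borderThreshold: 0.02
segmenter:
  epochs: 4
  patchesPerImage: 12
  patchSide: 32
  baseFilters: 8
  depth: 2
classifier:
  inputSide: 48
  trainResizeSide: 56
  epochs: 4
  batchSize: 32
  learningRate: 0.001
  brightnessJitter: 0.2
folds: 5
groupBySubject: true
attributionRadius: null      # null = 2x mean local vessel diameter
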