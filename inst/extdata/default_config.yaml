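# Default run configuration for the CAR analysis pipeline.
# Top-level keys mirror runConfig(); the generator block mirrors
# generatorConfig() overrides. Values shown are the package defaults.
simulate: true
periods: [24.0, 12.0]
averagedDay: false
countsScale: 15
ckWeights: [106, 54, 58, 76, 230, 74, 67]
ckScaleFactor: 0.001
ckThreshold: 1.0
gapToleranceMin: 10
onsetWindow: [18.0, 12.0]
nightWindow: [22.0, 7.0]
minValidFraction: 0.8
runScan: false
scanComponents: 720
alpha: 0.05
generator:
  seed: 1234
  nSubjects: 34
  nDays: 5
  epochSeconds: 60
  startDate: "2024-01-01"
  rhythm:
    c0: 0.20
    c1: 0.105
    c2: 0.09
    p1: 11.8
    p2: 12.0
    phaseMean: 0.3
    phaseSd: 1.2
  activity:
    gMean: 1.07
    gSdLog: 0.33
    gRange: [0.5, 1.36]
  noise:
    sdLog: 0.05
  sleep:
    bedMean: 21.84
    wakeMean: 6.21
    sleepExcess: 0.085
    arousalsPerNight: 6
  schedule:
    mealTimes: [7.0, 12.0, 18.0]
    lightsOut: 22.0
    lightsOn: 7.0
  effects:
    hypnoticsDelayH: 3.2
    hypnoticsMorningDamp: 0.5
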