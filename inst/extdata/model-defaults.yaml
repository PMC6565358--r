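# Versioned generator defaults for synthetic participants.
# Latency calibration values are trial-level means/SDs in ms; ERP component
# parameters give topography centre, temporal kernel and condition weights.
version: 1
behaviour:
  offsetMean: {terminated: 619.48, regular: 532.81, extended: 346.68}
  offsetSd: {terminated: 96.55, regular: 99.74, extended: 219.35}
  onsetMean: {learned: 788.02, new: 844.59}
  onsetSd: {learned: 168.00, new: 172.31}
  gainEffectMean: {gain: 178.54, no_gain: -45.40}
  gainEffectSd: {gain: 106.62, no_gain: 82.24}
  surpriseSlope: {gain: -150.0, no_gain: 0.0}   # ms per nat, centred coupling
  prematureReleaseRate: {gain: 0.12, no_gain: 0.02}
  missRate: 0.05
  faRate: 0.05
erp:
  samplingRate: 500
  window: [-100, 600]
  noiseSd: 3.0
  noiseSmoothing: 0.35
  components:
    - name: P3b
      centre: Pz
      spread: 0.35
      amplitude: 5.0
      width: 60
      peak: {PE: 388, CP: 420, STD: 388}
      weight: {PE: 1.0, CP: 1.0, STD: 0.0}
    - name: N400
      centre: Cz
      spread: 0.30
      amplitude: -3.0
      width: 50
      peak: {PE: 418, CP: 418, STD: 418}
      weight: {PE: 1.0, CP: 0.0, STD: 0.0}
    - name: P600
      centre: P6
      spread: 0.35
      amplitude: 2.5
      width: 70
      peak: {PE: 500, CP: 554, STD: 500}
      weight: {PE: 1.0, CP: 1.0, STD: 0.0}
    - name: earlyFrontal
      centre: Fz
      spread: 0.40
      amplitude: 3.0
      width: 40
      peak: {PE: 300, CP: 300, STD: 290}
      weight: {PE: 0.8, CP: 0.5, STD: 1.5}
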