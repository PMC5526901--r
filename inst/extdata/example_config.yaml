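# Example pipeline configuration: spike-in limit-of-detection experiment.
# Seven fivefold dilution steps of a donor carrying a 1.7% multimer+
# response (of live single lymphocytes) into a negative donor, run in
# duplicate with a pure-negative control, analyzed single-stage
# (DAG prefilter -> grid-density clustering -> cutoff-rule annotation).
mode: single-stage
panel: [FSC-A, FSC-H, SSC-A, viability, dump, CD3, CD8, multimer-PE]
design:
  f0: 1.7
  d: 5
  nSteps: 7
  nEventsPerSample: 200000
  duplicates: 2
  includePureNegative: true
  positivePreset: spikein1_positive
  negativePreset: spikein1_negative
cluster:
  bins: 12
annotate:
  thresholdEvents: 10
  multimerRoles: [multimer-PE]
seed: 1
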