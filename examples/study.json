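{
  "model": "rayleigh",
  "lambda_true": 0.125,
  "cells": [[10, 30], [10, 35], [15, 40], [20, 40]],
  "schemes": ["R1", "R2", "R3"],
  "priors": ["jeffreys", "uniform"],
  "uniform_bounds": [0, 3],
  "x0": 2.5,
  "reps": 10000,
  "seed": 1
}
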