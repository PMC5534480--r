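{
  "comment": "Example rigid registration matrix for a whole-brain light-microscopy dataset, estimated by a third-party registration tool on coarsely resampled data. Pure rotation, zero translation; row-major, applied to column vectors (x, y, z, 1).",
  "matrix": [
    [0.868588, -0.391007, -0.304410, 0],
    [0.273509, 0.89055, -0.363469, 0],
    [0.413211, 0.232447, 0.880467, 0],
    [0, 0, 0, 1]
  ]
}
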