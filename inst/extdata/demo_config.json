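{
  "out_dir": "demo_out",
  "seed": 1,
  "phantom": { "n": 64, "voxel_mm": 0.088, "noise_sd": 20 },
  "stages": { "filter": true, "decompose": true, "quantify": true,
              "report": true },
  "quantify": { "method": "both" }
}
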