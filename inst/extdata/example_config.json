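{
  "seed": 1,
  "output_dir": "flow4d_run",
  "phantom": {
    "kind": "poiseuille",
    "radius": 10,
    "length": 60,
    "spacing": [0.885, 0.885, 1.0],
    "flow_rate_lpm": 5
  },
  "degrade": {
    "target_spacing": [1.25, 1.25, 2.0],
    "noise_sd": 0.02,
    "venc": 1.5
  },
  "segment": {
    "frame": 1,
    "threshold": 0.05,
    "seed_voxel": [13, 13, 15],
    "connectivity": 26,
    "boundary_threshold": 0.02
  },
  "wss": {},
  "el": { "closure": "les_smagorinsky" },
  "flowrate": { "plane": { "origin": [0, 0, 30], "normal": [0, 0, 1] } },
  "compare": {
    "planes": [
      { "origin": [0, 0, 20], "normal": [0, 0, 1] },
      { "origin": [0, 0, 40], "normal": [0, 0, 1] }
    ]
  }
}
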