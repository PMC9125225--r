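{
  "coordinates": [{"name": "x1", "size": 2}, {"name": "x2", "size": 2}],
  "reservoirs": [
    {"name": "v1", "puppets": ["x1"], "leaders": ["x1"],
     "rates": {"mode": "explicit",
               "matrix": [[-0.7, 0.3], [0.7, -0.3]]}},
    {"name": "v2", "puppets": ["x2"], "leaders": ["x2"],
     "rates": {"mode": "random", "seed": 7, "scale": 1.0}}
  ],
  "protocol": [{"t0": 0.0, "t1": 1.0, "scale": 1.0},
               {"t0": 1.0, "t1": 2.0, "scale": 0.5}],
  "units": [["x1"], ["x2"]],
  "initial": {"mode": "delta", "state": [0, 1]},
  "time": {"ti": 0.0, "tf": 2.0},
  "n_steps": 600
}
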