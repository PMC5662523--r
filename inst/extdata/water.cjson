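{
  "chemicalJson": 1,
  "name": "water",
  "atoms": {
    "elements": {
      "number": [8, 1, 1]
    },
    "coords": {
      "3d": [0, 0, 0, 0.757, 0.586, 0, -0.757, 0.586, 0]
    }
  },
  "bonds": {
    "connections": {
      "index": [0, 1, 0, 2]
    },
    "order": [1, 1]
  }
}
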