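# Example synthetic-dataset specification for the `synth` subcommand:
# per-subtype image counts at (40x, 100x, 200x, 400x) and the render size.
counts:
  FI: [10, 0, 0, 0]
  DU: [10, 0, 0, 0]
image_size: [230, 350]
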