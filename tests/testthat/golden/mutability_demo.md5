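f2d87b3c979d1dfcc2d6d4e809c8963d
166836
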