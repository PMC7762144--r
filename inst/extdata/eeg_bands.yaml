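Theta: [4, 8]
Alpha: [8, 12]
Beta: [12, 30]
Gamma: [30, 50]
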