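# phantom generation
subdivisions = 2
frames = 60
snr_db = 20
seed = 1

# inverse pipeline
methods = MFS-ZOT, FEM-ZOT, FEM-L1
criteria = GCV, RGCV, CRESO
gamma = 0
beta = 1e-5
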