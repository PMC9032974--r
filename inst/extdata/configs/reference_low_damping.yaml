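# Low-damping reference circuit: intrinsic period 20 motif spacings,
# lam/k_n = 0.04. Keys mirror continuum_params().
W_EE: 1.2
W_EI: 0.573684
W_IE: 0.573684
W_II: 0.6
D_EE: 0.6
D_EI: 1.040453
D_IE: 1.040453
D_II: 0.25
tau_E: 1.0
alpha: 0.5
gamma_E: 0.0
gamma_I: 0.0
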