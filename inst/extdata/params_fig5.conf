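# Noise-figure preset (rates in 1/min, molecules); k0 from lambda0 = 1 -> beta_m0*beta_s
alpha_m = 1
alpha_s = 1
beta_m0 = 0.42
beta_s = 0.1
beta_p = 0.016666666666666666
k0 = 0.042
gamma0 = 1
x = 1
w = 1
y = 1
z = 0.001
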