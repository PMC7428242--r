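P = 23
q = 0.023
c_prime = 2e-05
f_star = 18
alpha1 = 1
alpha2 = 1
b1 = 0.3
b2 = 0.3
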