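# Base freeze-concentration scenario: 5 seed crystals, 5 vol% sucrose,
# 10 K initial supercooling, rapid cooling at 100 K/s.
n: 128
dt_tilde: 2.0e-4
t_end_tilde: 2.5
output_every_tilde: 0.1
phi_c0: 0.05
T_tilde0: -1.0
seeds:
  preset: base5
material:
  beta_f: 100
flow: true
gravity: true
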