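# scaffoldsim preset configuration
[scaffold]
side_mm = 10
n_layers = 10
young_modulus_kpa = 47

[protocol]
hours = 240
dt_hours = 1
media_change_hours = 24

[population]
n_vitro = 625000
cell_volume_mm3 = 4.2e-06
seed = 1

[celltypes]
P = proliferant
Q = quiescent
D = dead

[composition]
P = 1

[diffusion]
d_glucose_mm2_h = 2.412
d_oxygen_mm2_h = 10.8
media_glucose_g_l = 4.5
incubator_oxygen_g_l = 0.0072
medium_volume_ml = 1
glucose_boundary = reservoir
oxygen_boundary = dirichlet

[parameters]
a = 0.38
b = 0.005
c = 0.1
d = 0.15
e = 0.008
u_glu = 1.67e-11
u_o2 = 2.93e-15
u_ym = 1050
s = 0.5
lox = 3e-06

[rules]
dup: P -> P + P, a * min(Glc, O2)
qui: P -> Q, d * (1 - Glc)
rev: Q -> P, b * Glc
die_p: P -> D, c * (1 - Glc) * (1 - min(O2, 1))
die_q: Q -> D, c * (1 - Glc) * (1 - min(O2, 1))
mig: P -> empty + P, e
deg: D -> empty, a
upt_glc_p: P -> U, environment (Glc)
upt_glc_q: Q -> U, environment (Glc)
upt_o2_p: P -> U, environment (O2)
upt_o2_q: Q -> U, environment (O2)
stiff: P -> U, environment (YM)

[output]
snapshot_hours = 0 240
capacity_per_site = 1
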