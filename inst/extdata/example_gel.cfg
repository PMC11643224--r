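# Spheroid growing inside an agarose-like gel (nondimensional units:
# stresses in shear moduli, lengths in um, times in days).
k = 1            # chemical energy coefficient
eta = 1          # growth-rate scale (1/day)
gamma_c = 0.7    # nutrient uptake rate (1/day)
L = 65           # diffusion length (um)
beta = 0         # rearrangement rate (1/day)
K = 10           # bulk modulus (compressible variant only)

load_kind = gel
load_cH = 0.5        # gel rigidity relative to the tissue shear modulus
load_R0_gel = 20     # stress-free gel cavity radius (um)

R0 = 20          # initial spheroid radius (um)
t_max = 15       # simulated horizon (days)
variant = incompressible
N = 48           # grid nodes
dt = 0.005       # time step (days)
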