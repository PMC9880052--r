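# Wild-type mouse rod parameter set for the well-stirred phototransduction
# model. All concentrations are volumetric (uM) referred to the cytosolic
# outer-segment volume V_cyt; bimolecular rates in 1/(uM s); currents in pA.
# Provenance notes for every default are in the 'provenance' map below.
schema: pepperberg-params-1

# ---- cGMP synthesis: two Ca2+-inhibited guanylate cyclase components ----
alpha_min: 2.0        # uM/s, high-Ca2+ synthesis floor
alpha_max: 40.0       # uM/s, low-Ca2+ synthesis ceiling
beta: 0.15            # weight of the GCAP1-like (K_cyc1) component
K_cyc1: 0.047         # uM; GCAP1 K1/2 for Ca2+
K_cyc2: 0.133         # uM; GCAP2 K1/2 for Ca2+
m_cyc1: 1.5
m_cyc2: 1.5

# ---- cGMP hydrolysis by PDE subunits ----
k_hyd: 0.00911        # 1/(uM s), basal subunit (k_hyd * E0 = dark turnover)
k_sigma_hyd: 398.0    # 1/(uM s), activated subunit

# ---- CNG channel ----
j_cG_max: 1411.0      # pA at saturating cGMP
K_cG_min: 13.0        # uM, low-Ca2+ affinity
K_cG_max: 32.0        # uM, high-Ca2+ affinity
m_cG: 1.9             # Hill exponent for cGMP
m_CaM: 2.0            # Hill exponent of the calmodulin effect
K_CaM: 0.045          # uM Ca2+ for half-maximal calmodulin effect
f_Ca: 0.12            # fraction of CNG current carried by Ca2+

# ---- Na+/Ca2+,K+ exchanger ----
j_ex_sat: 6.28        # pA
K_ex: 1.6             # uM

# ---- calcium bookkeeping and geometry ----
B_Ca: 50.0            # dimensionless buffering capacity
F_const: 96500.0      # C/mol
V_cyt: 20.0           # um^3 cytosolic outer-segment volume

# ---- rhodopsin phosphorylation / arrestin chain ----
n_sites: 6            # maximum phosphorylations (mouse)
lambda_max: 60.0      # 1/s per state at low Ca2+ (uniform default)
mu_max: 60.0          # 1/s arrestin binding, states with >= 3 phosphates

# ---- recoverin / rhodopsin-kinase equilibrium ----
K1: 0.16              # uM, Ca2+ binding to recoverin
K2: 15.6              # uM, recoverin membrane partition
K3: 20.0              # uM, cytosolic recoverin-RK binding
K4: 2.0               # uM, membrane recoverin-RK binding
M_rec: 2.0            # uM, membrane partition weight
RK_tot: 7.0           # uM total rhodopsin kinase
Rec_tot: 35.0         # uM total recoverin

# ---- transducin / PDE / RGS9 front end ----
nu_RT: 170.0          # 1/s transducin activation per fully active R*
nu_per_state: 1.0     # relative catalytic activity per R* state
k_TE: 0.36            # 1/(uM s) T*--E formation
k_f: 0.0223861        # 1/(uM s) RGS9 binding to T*--E
k_b: 0.0627           # 1/s RGS9 dissociation
k_cat: 5.295          # 1/s GTP hydrolysis in RGS9--T*--E
T0: 800.0             # uM basal transducin
E0: 450.0             # uM basal PDE catalytic subunits
RGS9_0: 120.0         # uM basal RGS9 complex
k_E: 2.6247           # 1/s first-order E* shutoff (simplified variant)

# ---- analytic saturation theory ----
nu_RE: ~              # 1/s lumped R*->E* rate; null derives nu_RT
epsilon: 0.02         # criterion fraction defining exit from saturation

# ---- geometry ----
collecting_area: 0.45 # um^2, converts flash strength to photoisomerizations

provenance:
  alpha_min: assumed; chosen with alpha_max and the dark turnover to give a dark cGMP near 3 uM
  alpha_max: published mouse-rod range for maximal ROS-GC synthesis; adjusted within range
  beta: assumed; GCAP2 carries most wild-type cyclase regulation (overall K1/2 near 133 nM)
  K_cyc1: printed value; GCAP1 K1/2 46-47 nM
  K_cyc2: printed value; GCAP2 K1/2 133 nM
  m_cyc1: published GCAP cooperativity range 1.5-2.5
  m_cyc2: published GCAP cooperativity range 1.5-2.5
  k_hyd: set so k_hyd*E0 matches the published mouse dark cGMP turnover near 4.1 1/s
  k_sigma_hyd: published single-E* hydrolysis range; adjusted within range to reproduce saturation metrics
  j_cG_max: set so the dark circulating current is near 15 pA at the dark cGMP
  K_cG_min: printed value; channel affinity at low Ca2+ 13 uM
  K_cG_max: printed value; channel affinity at high Ca2+ 32 uM
  m_cG: published CNG Hill exponent range 2-3; low end reproduces the criterion-study intercept shift
  m_CaM: assumed; cooperative calmodulin action
  K_CaM: assumed within the sub-uM range bracketing dark Ca2+
  f_Ca: published mouse value 0.10-0.15
  j_ex_sat: set so the dark Ca2+ balance lands near 250 nM
  K_ex: published exchanger affinity near 1.6 uM
  B_Ca: assumed; gives a Ca2+ relaxation time of tens of ms
  F_const: physical constant
  V_cyt: mouse outer-segment cytosolic volume, published geometry
  n_sites: printed value; up to six phosphorylations in mouse
  lambda_max: published mouse R* phosphorylation range; uniform across states
  mu_max: assumed comparable to the phosphorylation rate
  K1: assumed; recoverin Ca2+ affinity in the published sub-uM range
  K2: source-model recoverin membrane partition constant
  K3: source-model recoverin-RK binding constant
  K4: source-model membrane recoverin-RK binding constant
  M_rec: source-model membrane partition weight
  RK_tot: published RK content of mouse rods (about 1 percent of rhodopsin)
  Rec_tot: published recoverin content; adjusted within range
  nu_RT: published transducin activation rate per R*, 120-300 1/s
  nu_per_state: assumed uniform; per-state profile not published
  k_TE: assumed fast T*-effector coupling (k_TE*E0 over 100 1/s)
  k_f: set with RGS9_0 so the RGS9-limited shutoff reproduces the printed time-constant family
  k_b: set with k_f and k_cat from the printed time-constant family
  k_cat: set from the printed time-constant family (fast-shutoff limit)
  T0: published transducin content, upper range (about 1:7 of rhodopsin)
  E0: PDE catalytic-subunit content; adjusted above the published ratio so full PDE activation occurs only at extreme flash strengths
  RGS9_0: RGS9 complex content; adjusted so stoichiometric depletion starts near LnPhi 11
  k_E: reciprocal of the wild-type dominant time constant
  nu_RE: derived from nu_RT (every activated transducin binds an effector subunit)
  epsilon: matches the 2 percent criterion recovery
  collecting_area: printed value 0.45 um^2
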