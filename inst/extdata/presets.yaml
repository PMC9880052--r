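# Mutant presets: parameter-override maps applied to a base parameter set.
# scale: multiply the field; set: replace the field; freeze_cyclase: pin the
# cGMP synthesis rate at its current dark-adapted value (removes the Ca2+
# feedback onto the cyclase while preserving the dark current).
WT:
  description: wild type (identity)
RGS9_0.2x:
  description: RGS9 complex underexpression to 0.2x
  scale: {RGS9_0: 0.2}
RGS9_2x:
  description: RGS9 complex overexpression to 2x
  scale: {RGS9_0: 2}
RGS9_4x:
  description: RGS9 complex overexpression to 4x
  scale: {RGS9_0: 4}
RK_0.3x:
  description: hemizygous rhodopsin kinase knockout; R* phosphorylation 3-fold slower
  scale: {lambda_max: 0.333333333333333}
RK_S561L:
  description: membrane-enhanced mutant kinase; R* phosphorylation 3-fold faster
  scale: {lambda_max: 3}
GCAP2_KO:
  description: GCAP2 knockout; low-Ca2+ maximal synthesis 40% of WT, overall K1/2 47 nM
  scale: {alpha_max: 0.4}
  set: {beta: 1.0}
GCAPs_KO:
  description: knockout of both GCAPs; cyclase frozen at the dark-adapted rate
  freeze_cyclase: true
CNG_CaM_null:
  description: CNG channel without calmodulin modulation; K_cG fixed at its low-Ca2+ minimum
  set: {K_cG_max: K_cG_min}
PDE_0.1x:
  description: PDE expression reduced 10-fold
  scale: {E0: 0.1}
PDE_10x:
  description: PDE expression increased 10-fold
  scale: {E0: 10}
Rec_KO:
  description: recoverin knockout; rhodopsin kinase fully available at all Ca2+
  set: {Rec_tot: 0}
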