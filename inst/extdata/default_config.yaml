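# Default parameter distributions for the peri-arterial wall model.
#
# Units in this file: lengths in micrometres, pressures in mmHg, everything
# else SI (permeabilities m^2, conductivities m/Pa/s, densities 1/m^2,
# drainage flux m^2/s). Converted to SI on load (133.322 Pa/mmHg exactly).
#
# Provenance tags:
#   [anchored]    value or level stated for this model system (coronary-scale
#                 wall, capillary vasa vasorum, physiologic interstitial
#                 pressures) or matching its published operating points.
#   [placeholder] documented assumption standing in for unavailable
#                 site-specific source tables; chosen once so that the
#                 healthy ensemble is near whole-tissue mass balance
#                 (mass-balance deviation ~ 1 at -2.5 mmHg test pressure,
#                 total lymph sink near 3e-5 1/s) and the inner-layer
#                 velocity sits in the measured 0.025-0.055 um/s window.
#                 Replace with transcribed literature distributions to run
#                 site-specific studies.

geometry:
  r_lu: {kind: gaussian, mean: 1500, sd: 100}   # [anchored] coronary lumen radius ~1.5 mm
  t_i:  {kind: gaussian, mean: 400, sd: 50}     # [anchored] intima+media thickness ~0.4 mm
  t_a:  {kind: gaussian, mean: 400, sd: 50}     # [anchored] adventitia thickness ~0.4 mm
  t_p:  {kind: gaussian, mean: 800, sd: 100}    # [placeholder] PVAT thickness ~0.8 mm

tissue:
  k_i: {kind: loguniform, low: 6.0e-19, high: 1.8e-18}  # [anchored] spans the published healthy levels (0.6-1.5e-18 m^2); keeps mid-wall velocity in the measured 0.025-0.055 um/s window
  k_a: {kind: loguniform, low: 3.0e-17, high: 3.0e-16}  # [placeholder] adventitia 1-2 orders more permeable than inner layers
  # k_p intentionally absent: defaults to the sampled k_a (PVAT resistance
  # is secondary on the transwall pathway).
  mu: 1.0e-3                                            # [anchored] interstitial fluid viscosity, Pa s

vasa:
  l_pv: {kind: loguniform, low: 1.4e-12, high: 5.6e-12} # [placeholder] capillary hydraulic conductivity range
  N_v:  {kind: loguniform, low: 6.0e+7, high: 1.6e+8}   # [placeholder] 60-160 vessels per mm^2 of wall cross-section
  d_v: 10                                               # [anchored] capillary diameter 10 um
  p_v:  {kind: gaussian, mean: 18, sd: 1}               # [placeholder] capillary hydrostatic pressure, mmHg
  pi_v: {kind: gaussian, mean: 20, sd: 1}               # [placeholder] effective vasa osmotic pressure, mmHg
  pi_t: {kind: gaussian, mean: 25.2, sd: 1}             # [placeholder] effective tissue osmotic pressure, mmHg. Only the
                                                        # combination p_v - sigma*(pi_t - pi_v) enters the model: these
                                                        # placeholders set the net filtration driving pressure at zero
                                                        # tissue pressure to a small ~13 mmHg, as the revised Starling
                                                        # principle implies
  sigma: 0.9                                            # [anchored] reflection coefficient of a continuous endothelium
  kappa_v: 3.0e-9                                       # [placeholder] endothelial solute permeability, m/s; overridden
                                                        # by the sampled diffusive flux ratio in solute ensembles

lymph:
  N_l: {kind: gaussian, mean: 2.0e+6, sd: 5.0e+5}       # [placeholder] ~2 lymphatic vessels per mm^2
  q_tilde_l: {kind: loguniform, low: 1.2e-11, high: 4.0e-11} # [anchored] spans the published per-vessel drainage levels (0.8-1.5e-11 m^2/s)
  l_bar_l: 1                                            # [anchored] vessel length per unit radial thickness, conventionally 1

boundary:
  p_lu: {kind: gaussian, mean: 100, sd: 5}              # [anchored] mean coronary luminal pressure, mmHg

# Atherosclerotic multiplication factors, applied to healthy draws.
# Directions follow the reported disease remodelling; magnitudes are
# [placeholder] values chosen once so that (i) the total lymphatic sink
# roughly doubles (3e-5 -> ~7e-5 1/s), (ii) the vasa filtration conductance
# l_pv*N_v grows several-fold more than lymph drainage, elevating tissue
# pressure, and (iii) the mid-wall velocity falls by about a third despite
# the more permeable inner layers (thicker plaque-bearing intima).
athero_factors:
  geometry:
    t_i: 2.5     # plaque-thickened inner layers
    t_a: 1.5     # thickened adventitia
  tissue:
    k_i: 2.0     # more permeable inner layers (published healthy/diseased pairs imply ~1.9-2)
  vasa:
    N_v: 2.5     # denser vasa vasorum
    l_pv: 2.7    # more conductive vasa endothelium
  lymph:
    N_l: 3.5     # denser lymphatics
    q_tilde_l: 0.65  # slower drainage per vessel
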