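# PPE shielding-layer fixtures.  Areal densities (density thickness,
# g/cm^2) are the experimentally determined values for each garment;
# elemental compositions of the proprietary layers were never published
# and are ASSUMED here (synthetic stand-ins chosen to be shielding-
# equivalent at photon energies; edit in place to refine).
# coverage: body region the garment shields (whole_body, torso, legs, head)
pb_sheet:
  label: "Reference Pb sheet (1.25 mm)"
  areal_density: 1.419
  density: 11.35
  coverage: torso
  assumed: false
  fractions: {Pb: 1.0}
opch90:
  label: "OPCH-90 reference suit (butyl rubber, no shielding layer)"
  areal_density: 0.053
  density: 1.2
  coverage: whole_body
  assumed: false
  fractions: {C: 0.8562, H: 0.1438}
hkx:
  label: "HKX 1558 Whole Body Anti-Radiation Wear (lead compounds in rubber)"
  areal_density: 0.40
  density: 2.9
  coverage: whole_body
  assumed: true
  fractions: {Pb: 0.54, C: 0.39, H: 0.05, O: 0.02}
demron_suit:
  label: "DEMRON Full Body Suit (PE/PVC with Sn/Ba salts)"
  areal_density: 0.13
  density: 1.6
  coverage: whole_body
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
demron_class2:
  label: "DEMRON Class 2 Full Body Suit"
  areal_density: 0.13
  density: 1.6
  coverage: whole_body
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
demron_vest_1ply:
  label: "DEMRON Radiation Torso Vest 1 Ply"
  areal_density: 0.32
  density: 1.6
  coverage: torso
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
demron_vest_2ply:
  label: "DEMRON Radiation Torso Vest 2 Ply"
  areal_density: 0.26
  density: 1.6
  coverage: torso
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
demron_vest_4ply:
  label: "DEMRON Radiation Torso Vest 4 Ply"
  areal_density: 0.47
  density: 1.6
  coverage: torso
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
df_vest_w1:
  label: "Df Vest W-1 mm (tungsten in resin)"
  areal_density: 1.12
  density: 6.0
  coverage: torso
  assumed: true
  fractions: {W: 1.0}
df_vest_w2:
  label: "Df Vest W-2 mm (tungsten in resin)"
  areal_density: 2.08
  density: 6.0
  coverage: torso
  assumed: true
  fractions: {W: 1.0}
biorubber_e400:
  label: "BIORUBBER E-400 Vest (lead alloys in rubber with limestone)"
  areal_density: 0.72
  density: 2.8
  coverage: torso
  assumed: true
  fractions: {Pb: 0.62, C: 0.22, H: 0.03, O: 0.09, Ca: 0.04}
biorubber_e600:
  label: "BIORUBBER E-600 Vest"
  areal_density: 1.61
  density: 2.8
  coverage: torso
  assumed: true
  fractions: {Pb: 0.62, C: 0.22, H: 0.03, O: 0.09, Ca: 0.04}
ied_rdd_shield:
  label: "DEMRON IED RDD Shield (non-worn)"
  areal_density: 3.97
  density: 1.7
  coverage: torso
  assumed: true
  fractions: {H: 0.06, C: 0.35, O: 0.06, Cl: 0.18, Sn: 0.20, Ba: 0.15}
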