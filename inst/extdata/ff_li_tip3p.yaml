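# 12-6 Lennard-Jones "compromise" (CM) set for divalent metal cations with
# TIP3P water (Li, Roberts, Chakravorty, Merz 2013), transcribed from the
# primary source; monovalent ions from the CHARMM36 additive set
# (Beglov & Roux). Verify against the originals before production use.
name: li_tip3p
water_model: TIP3P
ecc_factor: 1.0
combining_rule: lorentz-berthelot
provenance_notes: >
  Divalent ions: Li et al. 2013 CM parameter set for TIP3P, parametrized
  against hydration free energies (dG_solv) and ion-water coordination
  numbers (CN). Monovalent ions: CHARMM36 additive force field.
  Transcribed values; not fitted in this package.
ions:
  - {species: Mg2+, q: 2.0, epsilon_kJmol: 0.04268672, rmin_half_nm: 0.1360}
  - {species: Ca2+, q: 2.0, epsilon_kJmol: 0.71203622, rmin_half_nm: 0.1649}
  - {species: Sr2+, q: 2.0, epsilon_kJmol: 1.18774325, rmin_half_nm: 0.1776}
  - {species: Ba2+, q: 2.0, epsilon_kJmol: 1.97051266, rmin_half_nm: 0.1982}
  - {species: Na+,  q: 1.0, epsilon_kJmol: 0.19623960, rmin_half_nm: 0.1410750}
  - {species: Cl-,  q: -1.0, epsilon_kJmol: 0.62760000, rmin_half_nm: 0.2270}
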