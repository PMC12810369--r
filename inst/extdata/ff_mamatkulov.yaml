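# 12-6 Lennard-Jones set for alkaline-earth cations parametrized against
# hydration free energies, activity-coefficient derivatives (a_cc) and water
# residence times (tau) with TIP3P-class water (Mamatkulov & Schwierz),
# transcribed from the primary source; monovalent ions from CHARMM36.
# Verify against the originals before production use.
name: mamatkulov
water_model: TIP3P
ecc_factor: 1.0
combining_rule: lorentz-berthelot
provenance_notes: >
  Divalent ions: Mamatkulov-Schwierz set, parametrized against dG_solv,
  a_cc and tau. Monovalent ions: CHARMM36 additive force field.
  Transcribed values; not fitted in this package.
ions:
  - {species: Mg2+, q: 2.0, epsilon_kJmol: 0.05350000, rmin_half_nm: 0.1355}
  - {species: Ca2+, q: 2.0, epsilon_kJmol: 0.50630000, rmin_half_nm: 0.1662}
  - {species: Sr2+, q: 2.0, epsilon_kJmol: 0.93050000, rmin_half_nm: 0.1798}
  - {species: Ba2+, q: 2.0, epsilon_kJmol: 1.88730000, rmin_half_nm: 0.2001}
  - {species: Na+,  q: 1.0, epsilon_kJmol: 0.19623960, rmin_half_nm: 0.1410750}
  - {species: Cl-,  q: -1.0, epsilon_kJmol: 0.62760000, rmin_half_nm: 0.2270}
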