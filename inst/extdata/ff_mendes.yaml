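# ECC-scaled 12-6 Lennard-Jones set for Mg2+ and Ca2+ parametrized against
# neutron-scattering difference structure factors dS(Q) with scaled charges
# f = 0.80 (Mendes de Oliveira et al.), transcribed from the primary source;
# monovalent ions from CHARMM36. Verify against the originals before
# production use.
name: mendes
water_model: TIP4P
ecc_factor: 0.80
combining_rule: lorentz-berthelot
provenance_notes: >
  Divalent ions: Mendes de Oliveira et al. ECC set (f = 0.80), parametrized
  against neutron scattering difference structure factors dS(Q); Mg2+ and
  Ca2+ only. Monovalent ions: CHARMM36 additive force field. Transcribed
  values; not fitted in this package.
ions:
  - {species: Mg2+, q: 2.0, epsilon_kJmol: 0.10040000, rmin_half_nm: 0.1402}
  - {species: Ca2+, q: 2.0, epsilon_kJmol: 0.60250000, rmin_half_nm: 0.1681}
  - {species: Na+,  q: 1.0, epsilon_kJmol: 0.19623960, rmin_half_nm: 0.1410750}
  - {species: Cl-,  q: -1.0, epsilon_kJmol: 0.62760000, rmin_half_nm: 0.2270}
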