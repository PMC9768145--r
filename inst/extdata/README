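Packaged constant tables
========================

atomic_constants.csv
  Z, standard atomic weights (IUPAC 2021 abridged), Berger-Seltzer mean
  ionization potentials (eV), K-shell binding energies (keV, X-ray data
  booklet values) and K-alpha fluorescence line energies (keV) for the
  elements occurring in bone, mineral and collagen compositions.

mass_attenuation.csv
  Elemental total mass attenuation coefficients mu/rho (cm^2/g, coherent
  scattering included) on a 2-100 keV grid, compiled from the NIST XCOM
  photon cross-section database. Absorption edges of P and Ca are
  represented by paired rows just below/above the edge energy; lookups
  interpolate log-log within segments. Values are accurate to a few
  percent, which is adequate for the transmission and dose estimates made
  here (no acceptance-grade quantity depends on them).

materials.conf
  Material presets (atomic fractions + mass density in g/cm^3) for dry
  pike bone, its mineral phase and demineralized collagen matrix, in the
  key-value format readMaterialConfig() parses. Fractions are normalized
  on read.

reference_damage_values.csv
  Literature-reported relative damaged volumes, damage accumulation rates
  and sub-micron beam predictions for pike cleithrum bone irradiated at
  18 keV, used by compareToReference() as the comparison surface. These
  values are never used as fit targets inside the package.
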