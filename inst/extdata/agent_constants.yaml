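# Physical and pharmacologic constants for the volatile anesthetic agents.
# All values editable; the package reads this table at run time and never
# hard-codes agent constants.
#
# mac40_pct: minimum alveolar concentration (vol%) at the reference age of 40.
# gwp100:    100-year global warming potential relative to CO2. Per-agent
#            attribution follows the atmospheric-chemistry literature
#            (sevoflurane ~130, isoflurane ~510, desflurane ~2540); treat as
#            reported inventory values, not physical constants.
reference_temperature_c: 21
provenance: >
  Molecular weights and liquid densities from standard pharmacology
  references; GWP100 values from published atmospheric lifetime studies of
  halogenated anesthetics.
agents:
  - agent: sevoflurane
    mw_g_per_mol: 200.05
    density_g_per_ml: 1.520
    mac40_pct: 1.80
    gwp100: 130
  - agent: isoflurane
    mw_g_per_mol: 184.49
    density_g_per_ml: 1.496
    mac40_pct: 1.17
    gwp100: 510
  - agent: desflurane
    mw_g_per_mol: 168.04
    density_g_per_ml: 1.465
    mac40_pct: 6.60
    gwp100: 2540
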