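# Stylized dorsal-interneuron scenarios for the synthetic generator.
# Cluster means/covariances are in normalized (dv, ml) coordinates and
# encode qualitative anatomy (streams and clusters), not measured data.
geometry:
  H: {meanlog: 5.2983, sdlog: 0.08}   # ~200 px sections
  W: {meanlog: 4.6052, sdlog: 0.08}   # ~100 px hemicords
cells_per_section: 40
intensity: {background: 50, signal: 100, noise_sd: 10}
presets:
  dI2:
    populations:
      dI2:
        markers: [Foxd3, Brn3a]
        colabel: {Pou2f2: 0.3}
        clusters:
          - weight: 0.6      # dorso-medial stream near the progenitor domain
            mean: [0.78, 0.30]
            cov: [[0.012, 0.003], [0.003, 0.008]]
          - weight: 0.4      # ventral cluster
            mean: [0.35, 0.45]
            cov: [[0.010, 0.0], [0.0, 0.015]]
  dI3:
    populations:
      dI3:
        markers: [Isl1]
        clusters:
          - weight: 1.0      # single intermediate cluster
            mean: [0.55, 0.35]
            cov: [[0.012, 0.0], [0.0, 0.012]]
  dI5:
    populations:
      dI5:
        markers: [Lmx1b]
        clusters:
          - weight: 0.7      # medial major cluster
            mean: [0.60, 0.30]
            cov: [[0.010, 0.0], [0.0, 0.010]]
          - weight: 0.3      # lateral minor cluster
            mean: [0.55, 0.70]
            cov: [[0.008, 0.0], [0.0, 0.008]]
  dI6:
    populations:
      dI6:
        markers: [Dmrt3]
        colabel: {WT1: 0.3}
        clusters:
          - weight: 1.0      # ventro-medial cluster
            mean: [0.25, 0.20]
            cov: [[0.008, 0.002], [0.002, 0.008]]
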