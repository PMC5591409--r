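# Serum metabolite library for the synthetic 1H-NMR generator and the targeted
# quantifier.
#
# Schema
# ------
# reference:            internal standard (TSP), fixed concentration in mM
# metabolites:          list of metabolite entries
#   name:               unique metabolite name
#   multiplets:         first-order multiplets; center (ppm), multiplicity
#                       (line count, binomial 1:1 / 1:2:1 / ... intensity
#                       ratios), J (line spacing, Hz), protons (contributing
#                       1H), linewidth (Lorentzian half-width at half-maximum,
#                       Hz)
#   quant:              designated quantification window: index of the
#                       multiplet to integrate, margin (ppm) added on each side
#                       of the outer lines, overlap flag (true => a neighbouring
#                       species contributes to the window; quantified with a
#                       warning).  Entries without `quant` are not quantified
#                       (fully overlapped signals, e.g. the 0.92 ppm pair).
#   distributions:      per-class (C / R / NR) concentration mean and SD in mM,
#                       sampled as a normal truncated at 0.
#                       source: paper   => class means/SDs from the published
#                                          concentration table
#                       source: default => metabolite not in the published
#                                          table; ordered C < R < NR with
#                                          magnitudes in the 0.05-0.3 mM range
#
# Chemical shifts and J values are standard reference values for serum at
# physiological pH; they are implementation defaults and editable here.
reference:
  name: TSP
  concentration_mM: 0.507
  multiplets:
    - {center: 0.0, multiplicity: 1, J: 0.0, protons: 9, linewidth: 1.0}
  quant: {multiplet: 1, margin: 0.05, overlap: false}
metabolites:
  - name: 3-OH-butyrate
    multiplets:
      - {center: 1.20, multiplicity: 2, J: 6.3, protons: 3, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.04, overlap: false}
    distributions:
      C:  {mean: 0.10,  sd: 0.07, source: paper}
      R:  {mean: 0.12,  sd: 0.06, source: paper}
      NR: {mean: 0.14,  sd: 0.10, source: paper}
  - name: acetate
    multiplets:
      - {center: 1.92, multiplicity: 1, J: 0.0, protons: 3, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.05, overlap: false}
    distributions:
      C:  {mean: 0.061, sd: 0.01, source: paper}
      R:  {mean: 0.09,  sd: 0.02, source: paper}
      NR: {mean: 0.10,  sd: 0.02, source: paper}
  - name: acetoacetate
    multiplets:
      - {center: 2.27, multiplicity: 1, J: 0.0, protons: 3, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.015, overlap: false}
    distributions:
      C:  {mean: 0.01,  sd: 0.01, source: paper}
      R:  {mean: 0.02,  sd: 0.01, source: paper}
      NR: {mean: 0.03,  sd: 0.01, source: paper}
  - name: acetone
    multiplets:
      - {center: 2.23, multiplicity: 1, J: 0.0, protons: 6, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.02, overlap: false}
    distributions:
      C:  {mean: 0.0008, sd: 0.001, source: paper}
      R:  {mean: 0.008,  sd: 0.008, source: paper}
      NR: {mean: 0.02,   sd: 0.01,  source: paper}
  - name: citrate
    multiplets:
      - {center: 2.54, multiplicity: 2, J: 15.0, protons: 2, linewidth: 1.0}
      - {center: 2.66, multiplicity: 2, J: 15.0, protons: 2, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.03, overlap: false}
    distributions:
      C:  {mean: 0.12,  sd: 0.04, source: paper}
      R:  {mean: 0.10,  sd: 0.04, source: paper}
      NR: {mean: 0.09,  sd: 0.02, source: paper}
  - name: glucose
    multiplets:
      - {center: 5.23, multiplicity: 2, J: 3.8, protons: 1, linewidth: 1.0}
      - {center: 3.23, multiplicity: 1, J: 0.0, protons: 1, linewidth: 1.2}
      - {center: 3.42, multiplicity: 1, J: 0.0, protons: 1, linewidth: 1.2}
      - {center: 3.46, multiplicity: 1, J: 0.0, protons: 1, linewidth: 1.2}
      - {center: 3.53, multiplicity: 1, J: 0.0, protons: 1, linewidth: 1.2}
      - {center: 3.72, multiplicity: 1, J: 0.0, protons: 2, linewidth: 1.2}
    quant: {multiplet: 1, margin: 0.05, overlap: false}
    distributions:
      C:  {mean: 2.02,  sd: 0.05, source: paper}
      R:  {mean: 1.81,  sd: 0.03, source: paper}
      NR: {mean: 1.74,  sd: 0.03, source: paper}
  - name: lactate
    multiplets:
      - {center: 1.33, multiplicity: 2, J: 6.9, protons: 3, linewidth: 1.0}
      - {center: 4.11, multiplicity: 4, J: 6.9, protons: 1, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.05, overlap: false}
    distributions:
      C:  {mean: 1.88,  sd: 0.04, source: paper}
      R:  {mean: 1.72,  sd: 0.05, source: paper}
      NR: {mean: 1.16,  sd: 0.05, source: paper}
  - name: scyllo-inositol
    multiplets:
      - {center: 3.35, multiplicity: 1, J: 0.0, protons: 6, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.025, overlap: false}
    distributions:
      C:  {mean: 0.16,  sd: 0.01, source: paper}
      R:  {mean: 0.40,  sd: 0.50, source: paper}
      NR: {mean: 0.24,  sd: 0.20, source: paper}
  - name: choline
    multiplets:
      - {center: 3.19, multiplicity: 1, J: 0.0, protons: 9, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.015, overlap: true}
    distributions:
      C:  {mean: 0.05,  sd: 0.015, source: default}
      R:  {mean: 0.07,  sd: 0.02,  source: default}
      NR: {mean: 0.09,  sd: 0.02,  source: default}
  - name: alanine
    multiplets:
      - {center: 1.48, multiplicity: 2, J: 7.2, protons: 3, linewidth: 1.0}
    quant: {multiplet: 1, margin: 0.03, overlap: false}
    distributions:
      C:  {mean: 0.15,  sd: 0.04, source: default}
      R:  {mean: 0.22,  sd: 0.05, source: default}
      NR: {mean: 0.30,  sd: 0.06, source: default}
  - name: glutamate
    multiplets:
      - {center: 2.08, multiplicity: 3, J: 7.0, protons: 2, linewidth: 1.2}
      - {center: 2.35, multiplicity: 3, J: 7.0, protons: 2, linewidth: 1.2}
    quant: {multiplet: 2, margin: 0.03, overlap: false}
    distributions:
      C:  {mean: 0.08,  sd: 0.02, source: default}
      R:  {mean: 0.10,  sd: 0.03, source: default}
      NR: {mean: 0.12,  sd: 0.03, source: default}
  - name: 2-OH-butyrate
    multiplets:
      - {center: 0.92, multiplicity: 3, J: 7.4, protons: 3, linewidth: 1.0}
    distributions:
      C:  {mean: 0.05,  sd: 0.02, source: default}
      R:  {mean: 0.08,  sd: 0.03, source: default}
      NR: {mean: 0.10,  sd: 0.03, source: default}
  - name: 2-OH-valerate
    multiplets:
      - {center: 0.92, multiplicity: 3, J: 7.4, protons: 3, linewidth: 1.0}
    distributions:
      C:  {mean: 0.05,  sd: 0.02, source: default}
      R:  {mean: 0.07,  sd: 0.02, source: default}
      NR: {mean: 0.09,  sd: 0.03, source: default}
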