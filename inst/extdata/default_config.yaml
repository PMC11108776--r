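# Pipeline configuration with the analysis defaults. Every threshold
# the analysis uses is surfaced here; omitted keys fall back to the
# package defaults (see ?default_config).
seed: 1
radius: 50              # interaction radius, micrometres
compartment: tumor      # analysis compartment (stroma kept behind this flag)
msi_threshold: 3.5      # MSIsensor score for MSI-H, boundary inclusive
test: chisq             # 2x2 test for dichotomized biomarkers (or: fisher)
cutoff: tertile         # dichotomization rule (bottom tertile)
simulate: true
model_parameters:
  - pct_CD8_PD1_TOX_of_CD8
  - frac_PDL1_within{radius}_of_CD8PD1
designs:
  orr:   {n1: 23, r1: 1, n: 40, r: 5,  p0: 0.05, p1: 0.25}
  pfs24: {n1: 17, r1: 4, n: 40, r: 15, p0: 0.25, p1: 0.50}
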