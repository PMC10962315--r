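# PBMC T/B panel: 26 surface markers + viability dye (27 fluorophores).
# Signatures are synthetic 48-detector profiles (see signatures/ directory).
panel: tb
name: "PBMC T- and B-cell panel"
cofactor: 6000
viability: ViaDye
signatures: ../signatures/tb_signatures_synthetic.csv
markers:
  - CD45
  - CD3
  - CD4
  - CD8
  - CD45RA
  - CD197
  - CD27
  - CD28
  - CD185
  - CD183
  - CD25
  - CD127
  - CD194
  - CD196
  - CD161
  - TCRgd
  - TCRab
  - HLA-DR
  - CD38
  - CD19
  - CD20
  - IgD
  - CD279
  - CD366
  - CD223
  - CD152
  - ViaDye
gates:
  - name: Lymphocytes
    parent: root
    rect: {x: FSC-A, "y": SSC-A, xmin: 28000, xmax: 70000, ymin: 0, ymax: 42000}
    profile: lymphocyte
    canonical: false
  - {name: Total T cells, parent: Lymphocytes, expr: "CD3+", canonical: true}
  - {name: CD8 T cells, parent: Total T cells, expr: "CD4-/CD8+", canonical: true}
  - {name: Naive CD8, parent: CD8 T cells, expr: "CD45RA+/CD197+", canonical: true}
  - {name: TEMRA CD8, parent: CD8 T cells, expr: "CD45RA+/CD197-", canonical: true}
  - {name: CD45RA terminal effector CD8, parent: TEMRA CD8, expr: "CD27-/CD28-", canonical: true}
  - {name: Central memory CD8, parent: CD8 T cells, expr: "CD45RA-/CD197+", canonical: true}
  - {name: Effector CD8, parent: CD8 T cells, expr: "CD45RA-/CD197-", canonical: true}
  - {name: Early effector CD8, parent: Effector CD8, expr: "CD28+/CD27+", canonical: true}
  - {name: Early-like effector CD8, parent: Effector CD8, expr: "CD28+/CD27-", canonical: true}
  - {name: Terminal effector CD8, parent: Effector CD8, expr: "CD28-/CD27-", canonical: true}
  - {name: Intermediate effector CD8, parent: Effector CD8, expr: "CD28-/CD27+", canonical: true}
  - {name: CD4 T cells, parent: Total T cells, expr: "CD8-/CD4+", canonical: true}
  - {name: Naive CD4, parent: CD4 T cells, expr: "CD45RA+/CD197+", canonical: true}
  - {name: TEMRA CD4, parent: CD4 T cells, expr: "CD45RA+/CD197-", canonical: true}
  - {name: CD45RA terminal effector CD4, parent: TEMRA CD4, expr: "CD27-/CD28-", canonical: true}
  - {name: Central memory CD4, parent: CD4 T cells, expr: "CD45RA-/CD197+", canonical: true}
  - {name: Follicular helper T, parent: Central memory CD4, expr: "CD185+", canonical: true}
  - {name: Effector CD4, parent: CD4 T cells, expr: "CD45RA-/CD197-", canonical: true}
  - {name: Early effector CD4, parent: Effector CD4, expr: "CD28+/CD27+", canonical: true}
  - {name: Early-like effector CD4, parent: Effector CD4, expr: "CD28+/CD27-", canonical: true}
  - {name: Terminal effector CD4, parent: Effector CD4, expr: "CD28-/CD27-", canonical: true}
  - {name: Intermediate effector CD4, parent: Effector CD4, expr: "CD28-/CD27+", canonical: true}
  - {name: Regulatory T cells, parent: CD4 T cells, expr: "CD25+/CD127-", canonical: true}
  - {name: Th1, parent: CD4 T cells, expr: "CD183+/CD196-", canonical: true}
  - {name: Th2, parent: CD4 T cells, expr: "CD194+/CD196-", canonical: true}
  - {name: Th9/22, parent: CD4 T cells, expr: "CD183-/CD196+/CD194+", canonical: true}
  - {name: Th17, parent: CD4 T cells, expr: "CD161+/CD196+", canonical: true}
  - {name: Gamma delta T cells, parent: Total T cells, expr: "TCRgd+", canonical: true}
  - {name: gdT CD197-/CD45RAhi, parent: Gamma delta T cells, expr: "CD197-/CD45RAhi", canonical: true}
  - {name: gdT CD197+, parent: Gamma delta T cells, expr: "CD197+", canonical: true}
  - {name: gdT CD197-/CD45RA-, parent: Gamma delta T cells, expr: "CD197-/CD45RA-", canonical: true}
  - {name: Activated T cells, parent: Total T cells, expr: "HLA-DR+/CD38+", canonical: true}
  - {name: NKT-like cells, parent: Total T cells, expr: "TCRgd-/CD161+", canonical: true}
  - {name: NK cells, parent: Lymphocytes, expr: "CD3-/TCRgd-/TCRab-/HLA-DR-", canonical: true}
  - {name: Total B cells, parent: Lymphocytes, expr: "CD19+", canonical: true}
  - {name: Plasmablasts, parent: Total B cells, expr: "CD27+/CD38+", canonical: true}
  - {name: CD20+ B cells, parent: Total B cells, expr: "CD20+", canonical: true}
  - {name: Naive B, parent: CD20+ B cells, expr: "CD27-/IgD+", canonical: true}
  - {name: Switched memory B, parent: CD20+ B cells, expr: "CD27+/IgD-", canonical: true}
  - {name: Unswitched memory B, parent: CD20+ B cells, expr: "CD27+/IgD+", canonical: true}
  - {name: DN memory B, parent: CD20+ B cells, expr: "CD27-/IgD-", canonical: true}
overlays:
  PD-1: "CD279+"
  TIM-3: "CD366+"
  LAG-3: "CD223+"
  CTLA-4: "CD152+"
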