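# PBMC M/N/D panel (monocytes, NK, dendritic cells): 24 surface markers +
# viability dye (25 fluorophores). Synthetic 48-detector signatures.
panel: mnd
name: "PBMC monocyte / NK / dendritic-cell panel"
cofactor: 6000
viability: ViaDye
signatures: ../signatures/mnd_signatures_synthetic.csv
markers:
  - CD45
  - CD3
  - CD56
  - CD19
  - CD14
  - CD7
  - CD16
  - HLA-DR
  - CD11b
  - CD33
  - CD123
  - CD141
  - CD1c
  - CD5
  - CD163
  - CD20
  - CD94
  - CD314
  - CD159c
  - CD337
  - CD335
  - CD336
  - CD158
  - CD366
  - ViaDye
gates:
  - name: Lymphocytes
    parent: root
    rect: {x: FSC-A, "y": SSC-A, xmin: 28000, xmax: 70000, ymin: 0, ymax: 42000}
    profile: lymphocyte
    canonical: false
  - name: Monocytes
    parent: root
    rect: {x: FSC-A, "y": SSC-A, xmin: 70000, xmax: 120000, ymin: 35000, ymax: 95000}
    profile: monocyte
    canonical: false
  - {name: NKT cells, parent: Lymphocytes, expr: "CD3+/CD56+", canonical: true}
  - {name: NK cells, parent: Lymphocytes, expr: "CD3-/CD19-/CD14-/CD7+", canonical: true}
  - {name: Early NK cells, parent: NK cells, expr: "CD56+/CD16-", canonical: true}
  - {name: Mature NK cells, parent: NK cells, expr: "CD56+/CD16+", canonical: true}
  - {name: Terminal NK cells, parent: NK cells, expr: "CD56-/CD16+", canonical: true}
  - {name: Classical monocytes, parent: Monocytes, expr: "CD14+/CD16-", canonical: true}
  - {name: Classical monocytes-Normal, parent: Classical monocytes, expr: "HLA-DR+", canonical: true}
  - {name: Classical monocytes-Immunosuppressed, parent: Classical monocytes, expr: "HLA-DR-", canonical: true}
  - {name: Intermediate monocytes, parent: Monocytes, expr: "CD14+/CD16+", canonical: true}
  - {name: Intermediate monocytes-Normal, parent: Intermediate monocytes, expr: "HLA-DR+", canonical: true}
  - {name: Intermediate monocytes-Immunosuppressed, parent: Intermediate monocytes, expr: "HLA-DR-", canonical: true}
  - {name: Nonclassical monocytes, parent: Monocytes, expr: "CD14-/CD16+", canonical: true}
  - {name: Nonclassical monocytes-Normal, parent: Nonclassical monocytes, expr: "HLA-DR+", canonical: true}
  - {name: Nonclassical monocytes-Immunosuppressed, parent: Nonclassical monocytes, expr: "HLA-DR-", canonical: true}
  - {name: MDSC-like cells, parent: Monocytes, expr: "CD11b+/CD33+/HLA-DR-", canonical: true}
  - {name: Monocytic MDSC-like cells, parent: MDSC-like cells, expr: "CD14+", canonical: true}
  - {name: Dendritic cells, parent: Monocytes, expr: "CD3-/HLA-DR+/CD19-/CD20-", canonical: true}
  - {name: pDC, parent: Dendritic cells, expr: "CD14-/CD123+/CD141-/CD1c-/CD5-", canonical: true}
  - {name: cDC1, parent: Dendritic cells, expr: "CD14-/CD123-/CD141+/CD1c-/CD5-", canonical: true}
  - {name: cDC2, parent: Dendritic cells, expr: "CD14-/CD123-/CD141-/CD1c+/CD5+/CD11b+", canonical: true}
  - {name: cDC3, parent: Dendritic cells, expr: "CD163+/CD5-", canonical: true}
overlays:
  KLRD1: "CD94+"
  NKG2D: "CD314+"
  NKG2C: "CD159c+"
  NKp30: "CD337+"
  NKp46: "CD335+"
  NKp44: "CD336+"
  KIR: "CD158+"
  TIM-3: "CD366+"
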