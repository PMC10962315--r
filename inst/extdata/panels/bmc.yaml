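# Bone-marrow cell panel: 31 surface markers + viability dye (32 fluorophores).
# Synthetic 48-detector signatures.
panel: bmc
name: "Bone marrow cell panel"
cofactor: 6000
viability: ViaDye
signatures: ../signatures/bmc_signatures_synthetic.csv
markers:
  - CD45
  - CD3
  - CD34
  - TCRab
  - TCRgd
  - CD56
  - CD4
  - CD8
  - CD45RA
  - CD197
  - CD25
  - CD127
  - CD38
  - CD90
  - CD10
  - CD135
  - CD19
  - CD20
  - CD16
  - CD14
  - HLA-DR
  - CD11b
  - CD33
  - CD123
  - CD11c
  - CD274
  - CD366
  - CD163
  - CD206
  - CD74
  - CD80
  - ViaDye
gates:
  - {name: Total T cells, parent: root, expr: "CD3+/CD34-", canonical: true}
  - {name: Gamma delta T cells, parent: Total T cells, expr: "TCRgd+", canonical: true}
  - {name: abT cells, parent: Total T cells, expr: "TCRgd-/TCRab+", canonical: false}
  - {name: NKT cells, parent: abT cells, expr: "CD56+", canonical: true}
  - {name: NKT CD8+, parent: NKT cells, expr: "CD8+", canonical: true}
  - {name: NKT CD8-, parent: NKT cells, expr: "CD8-", canonical: true}
  - {name: CD56- T cells, parent: abT cells, expr: "CD56-", canonical: false}
  - {name: CD8 T cells, parent: CD56- T cells, expr: "CD4-/CD8+", canonical: true}
  - {name: Effector CD8, parent: CD8 T cells, expr: "CD45RA-/CD197-", canonical: true}
  - {name: Central memory CD8, parent: CD8 T cells, expr: "CD45RA-/CD197+", canonical: true}
  - {name: Naive CD8, parent: CD8 T cells, expr: "CD45RA+/CD197+", canonical: true}
  - {name: TEMRA CD8, parent: CD8 T cells, expr: "CD45RA+/CD197-", canonical: true}
  - {name: CD4 T cells, parent: CD56- T cells, expr: "CD4+/CD8-", canonical: true}
  - {name: Effector CD4, parent: CD4 T cells, expr: "CD45RA-/CD197-", canonical: true}
  - {name: Central memory CD4, parent: CD4 T cells, expr: "CD45RA-/CD197+", canonical: true}
  - {name: Naive CD4, parent: CD4 T cells, expr: "CD45RA+/CD197+", canonical: true}
  - {name: TEMRA CD4, parent: CD4 T cells, expr: "CD45RA+/CD197-", canonical: true}
  - {name: Regulatory T cells, parent: CD4 T cells, expr: "CD25+/CD127-", canonical: true}
  - {name: Progenitors, parent: root, expr: "CD3-/CD34+", canonical: false}
  - {name: CD38- progenitors, parent: Progenitors, expr: "CD38-", canonical: false}
  - {name: HSC, parent: CD38- progenitors, expr: "CD45RA-/CD90+", canonical: true}
  - {name: MPP, parent: CD38- progenitors, expr: "CD45RA-/CD90-", canonical: true}
  - {name: MLP, parent: CD38- progenitors, expr: "CD45RA+/CD90-", canonical: true}
  - {name: MLP I, parent: MLP, expr: "CD10-", canonical: true}
  - {name: MLP II, parent: MLP, expr: "CD10+", canonical: true}
  - {name: CD38+ progenitors, parent: Progenitors, expr: "CD38+", canonical: false}
  - {name: CD10- progenitors, parent: CD38+ progenitors, expr: "CD10-", canonical: false}
  - {name: CMP, parent: CD10- progenitors, expr: "CD45RA-/CD135+", canonical: true}
  - {name: GMP, parent: CD10- progenitors, expr: "CD45RA+/CD135+", canonical: true}
  - {name: MEP, parent: CD10- progenitors, expr: "CD45RA-/CD135-", canonical: true}
  - {name: CD10+ progenitors, parent: CD38+ progenitors, expr: "CD10+", canonical: true}
  - {name: CD3-CD34- cells, parent: root, expr: "CD3-/CD34-", canonical: false}
  - {name: B lineage, parent: CD3-CD34- cells, expr: "CD19+", canonical: false}
  - {name: B cells, parent: B lineage, expr: "CD20+", canonical: true}
  - {name: Plasmablasts, parent: B lineage, expr: "CD20-/CD38+", canonical: true}
  - {name: Non-B cells, parent: CD3-CD34- cells, expr: "CD19-/CD20-", canonical: false}
  - {name: Classical monocytes, parent: Non-B cells, expr: "CD14+/CD16-", canonical: true}
  - {name: Nonclassical monocytes, parent: Non-B cells, expr: "CD14-/CD16+/HLA-DR+", canonical: true}
  - {name: NK cells, parent: Non-B cells, expr: "CD14-/HLA-DR-/CD127-", canonical: true}
  - {name: Early NK, parent: NK cells, expr: "CD56+/CD16-", canonical: true}
  - {name: Mature NK, parent: NK cells, expr: "CD56+/CD16+", canonical: true}
  - {name: Terminal NK, parent: NK cells, expr: "CD16+/CD56-", canonical: true}
  - {name: Dendritic cells, parent: Non-B cells, expr: "CD14-/HLA-DR+", canonical: true}
  - {name: pDC, parent: Dendritic cells, expr: "CD123+/CD11c-", canonical: true}
  - {name: cDC, parent: Dendritic cells, expr: "CD11c+/CD123-", canonical: false}
  - {name: CD16+ cDC, parent: cDC, expr: "CD16+", canonical: true}
  - {name: CD16- cDC, parent: cDC, expr: "CD16-", canonical: true}
  - {name: ILCs, parent: Non-B cells, expr: "CD14-/HLA-DR-/CD123-/CD127+", canonical: true}
  - {name: MDSC-like, parent: Non-B cells, expr: "CD14+/HLA-DR-/CD11b+/CD33+", canonical: true}
overlays:
  PD-L1: "CD274+"
  TIM-3: "CD366+"
  CD163: "CD163+"
  CD206: "CD206+"
  CD74: "CD74+"
  CD80: "CD80+"
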