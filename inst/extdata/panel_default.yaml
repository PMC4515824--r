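name: default 35-spot leukocyte panel
spot_diameter_mm: 1.5
spots:
- row: 1
  col: 1
  cd: CD1a
- row: 1
  col: 2
  cd: CD2
- row: 1
  col: 3
  cd: CD3
- row: 1
  col: 4
  cd: CD4
- row: 1
  col: 5
  cd: CD5
- row: 1
  col: 6
  cd: CD7
- row: 1
  col: 7
  cd: CD8
- row: 2
  col: 1
  cd: CD10
- row: 2
  col: 2
  cd: CD11c
- row: 2
  col: 3
  cd: CD14
- row: 2
  col: 4
  cd: CD15
- row: 2
  col: 5
  cd: CD16
- row: 2
  col: 6
  cd: CD19
- row: 2
  col: 7
  cd: CD20
- row: 3
  col: 1
  cd: CD21
- row: 3
  col: 2
  cd: CD22
- row: 3
  col: 3
  cd: CD23
- row: 3
  col: 4
  cd: CD25
- row: 3
  col: 5
  cd: CD33
- row: 3
  col: 6
  cd: CD38
- row: 3
  col: 7
  cd: CD41a
- row: 4
  col: 1
  cd: CD43
- row: 4
  col: 2
  cd: CD45
- row: 4
  col: 3
  cd: CD45RA
- row: 4
  col: 4
  cd: CD45RO
- row: 4
  col: 5
  cd: CD56
- row: 4
  col: 6
  cd: CD61
- row: 4
  col: 7
  cd: CD64
- row: 5
  col: 1
  cd: CD103
- row: 5
  col: 2
  cd: HLA-DR
- row: 5
  col: 3
  cd: IgGk
- row: 5
  col: 4
  cd: IgGl
- row: 5
  col: 5
  cd: IgM
- row: 5
  col: 6
  cd: CD117
- row: 5
  col: 7
  cd: mIgG
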