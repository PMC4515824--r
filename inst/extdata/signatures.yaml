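CLL:
  disease: CLL
  expect:
    CD19: up
    CD20: variable
    CD22: variable
    CD23: up
    CD5: up
    CD2: down
    CD3: down
    CD4: down
    CD7: down
    CD8: down
  evidence: ~
HCL:
  disease: HCL
  expect:
    CD19: up
    CD20: up
    CD22: up
    CD25: up
    CD11c: up
    CD103: up
    CD5: down
    CD23: normal
    CD2: down
    CD3: down
    CD4: down
    CD7: down
    CD8: down
  evidence:
    trap: yes
    morphotype: hairy
SMZL:
  disease: SMZL
  expect:
    CD19: up
    CD20: up
    CD22: up
    CD25: up
    CD5: down
    CD23: normal
    CD11c: normal
    CD103: normal
    CD2: down
    CD3: down
    CD4: down
    CD7: down
    CD8: down
  evidence: ~
MCL:
  disease: MCL
  expect:
    CD19: up
    CD20: up
    CD22: up
    CD5: up
    CD23: normal
    CD2: down
    CD3: down
    CD4: down
    CD7: down
    CD8: down
  evidence: ~
FL:
  disease: FL
  expect:
    CD19: up
    CD20: up
    CD22: up
    CD10: up
    CD5: down
    CD2: down
    CD3: down
    CD4: down
    CD7: down
    CD8: down
  evidence: ~
normal:
  disease: normal
  expect: []
  evidence: ~
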