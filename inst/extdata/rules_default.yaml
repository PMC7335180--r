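# Default group-class constraint rules for AD/PD-like longitudinal cohorts.
# Edges are allowed unless a rule forbids them; the most specific matching
# rule wins. Temporal ordering and auxiliary-node topology are always
# enforced by expand_constraints() and need no rules here.
rules:
  # demographic baseline features influence others but are never influenced
  - {from: "*", to: "demographic", direction: "forbidden"}
  # imaging features may relate to each other but do not drive other groups
  - {from: "imaging", to: "*", direction: "forbidden"}
  - {from: "imaging", to: "imaging", direction: "allowed"}
  # clinical diagnosis depends on cognition scores, never the reverse
  - {from: "diagnosis", to: "cognition", direction: "forbidden"}
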