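# Default analysis configuration for human GDAP1 (reference numbering of
# NP_061845.2, as used in the wild-type crystal structure 7ALM).
#
# The helix residue ranges below are CURATOR-SUPPLIED: helix boundaries are
# not part of any machine-readable annotation shipped with the structures,
# so these ranges were chosen to be consistent with the residues commonly
# assigned to the core helices (Arg120/His123 on a3, the a6 C-terminal
# stretch 218-227, Cys240 in the a6-a7 loop, 247-262 spanning a7, Arg282 on
# a8). Adjust them to your own secondary-structure assignment if needed.

reference_id: NP_061845.2
group_rules:
  GDAP1: ["gdap1"]
  GST: ["transferase", "gst"]
drop_patterns: ["hypothetical", "putative"]
contrast: [GDAP1, GST]

s_conserved: 0.2     # entropy below this: conserved
s_highly: 0.1        # entropy below this: highly conserved
frac_min: 0.7        # minimum non-gap fraction for reporting
pseudocount: 0.5     # additive smoothing for KL divergence
k_representatives: 100

chain: A
helices:
  - {name: a3, chain: A, start: 116, end: 130}
  - {name: a6, chain: A, start: 191, end: 235}
  - {name: a7, chain: A, start: 247, end: 262}
  - {name: a8, chain: A, start: 275, end: 290}
# loop between a6 and a7 that inserts into the fold core
focus: [236, 237, 238, 239, 240, 241, 242, 243, 244, 245, 246]

contact:
  h_max: 3.5         # hydrogen-bond donor-acceptor cutoff, Angstrom
  angle_min: 90      # antecedent-donor-acceptor angle, degrees
  i_max: 4.0         # ionic (salt-bridge) N-O cutoff, Angstrom

# residues with reported Charcot-Marie-Tooth missense mutations
cmt_sites: [120, 123, 161, 218, 219, 222, 226, 227, 238, 239, 240, 247, 256, 282, 310]
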