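# Apelin-receptor (APJR, UniProt P35414 numbering) binding-site registry.
#
# BS1 is the pocket interior engaged by the hydrophobic C-terminal half of
# apelin; BS2/BS3 are the exterior acidic patches that stabilise the charged
# N-terminal half; BScritical collects residues whose mutation abolishes
# peptide binding. The per-site memberships below are approximate: the
# published assignment is conveyed by structure-figure coloring only, so these
# entries are figure-derived and meant to be edited when better lists exist.
# The `contacts` entry is the exact text-stated contact-residue list used to
# build the docking grid box.
sites:
  - name: BS1
    chain: A
    residues: [85, 88, 93, 182, 264, 268, 271, 284, 291, 299]
    source: "pocket interior; figure-derived approximation, editable"
  - name: BS2
    chain: A
    residues: [22, 24, 175, 176, 177]
    source: "exterior acidic patch; figure-derived approximation, editable"
  - name: BS3
    chain: A
    residues: [178, 195, 281, 282, 283]
    source: "exterior acidic patch; figure-derived approximation, editable"
  - name: BScritical
    chain: A
    residues: [88, 93, 264, 268, 271, 284, 299]
    source: "mutations abolishing binding; figure-derived approximation, editable"
  - name: contacts
    chain: A
    residues: [22, 24, 85, 88, 93, 175, 176, 177, 178, 182, 195, 264, 268, 271, 284, 291, 299]
    source: "docking grid contact list (T22 W24 W85 Y88 Y93 N175 T176 T177 K178 Y182 W195 Y264 K268 Y271 D284 F291 Y299)"
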