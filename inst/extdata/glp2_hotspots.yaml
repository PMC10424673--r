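# Canonical GLP-2 scaffold configuration: the receptor-bound helix
# (residues 1-31), its three overlapping segments and the nine
# activity hotspots established by alanine scanning.
sequence: HADGSFSDEMNTILDNLAARDFINWLIQTKI
chain: A
segments:
  helix1:
    start: 1
    end: 14
    hotspots:
      - {seq_id: 1, res_name: HIS}
      - {seq_id: 6, res_name: PHE}
      - {seq_id: 9, res_name: GLU}
  helix2:
    start: 7
    end: 19
    hotspots:
      - {seq_id: 8, res_name: ASP}
      - {seq_id: 14, res_name: LEU}
      - {seq_id: 17, res_name: LEU}
  helix3:
    start: 15
    end: 31
    hotspots:
      - {seq_id: 21, res_name: ASP}
      - {seq_id: 22, res_name: PHE}
      - {seq_id: 25, res_name: TRP}
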