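# Reference inputs for the worked-example checks

The worked-example acceptance tests compare against published values for two
human candidate chemokines and one viral chemokine template. The inputs are
not redistributed with the package; to run those checks, place plain-text
copies here:

- `Q1T7F1.fasta` — UniProt entry Q1T7F1 (the 81-residue candidate), FASTA:
  <https://rest.uniprot.org/uniprotkb/Q1T7F1.fasta>
- `Q71RG6.fasta` — UniProt entry Q71RG6 (the 208-residue candidate), FASTA:
  <https://rest.uniprot.org/uniprotkb/Q71RG6.fasta>
- `1ZXT.pdb` — PDB entry 1ZXT (vMIP-I), PDB format:
  <https://files.rcsb.org/download/1ZXT.pdb>

With the files present, the tests verify the theoretical monoisotopic mass of
the GA-tagged Q1T7F1 construct with three disulfide bonds (8,931.1423 Da,
Δm = +0.0662 Da against the measured 8,931.2085 Da), the cysteine counts
(6; 12; 8 within residues 53–208), and the three disulfide bonds mappable
onto 1ZXT chain A. Without them, those three tests report failures; all
other functionality is covered by the synthetic fixtures.
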