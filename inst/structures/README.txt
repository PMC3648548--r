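Drop user-supplied PDB coordinate files here (e.g. 4f8h.pdb, 4ire.pdb,
2bg9.pdb) or point options(allopath.structure_dir=) at a directory that
contains them. The package never downloads coordinates itself.
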