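# Crystal structures (not redistributed)

The hinge-angle validation against the LAO crystal structures needs two
PDB files that are not shipped with the package:

- `2LAO.pdb` — open (apo) form
- `1LAF.pdb` — closed (holo) form, the angular reference

Download them from the Protein Data Bank (https://files.rcsb.org/download/)
and place them in this directory before installing, e.g.

```sh
curl -O https://files.rcsb.org/download/2LAO.pdb
curl -O https://files.rcsb.org/download/1LAF.pdb
```

With the files present, `opening_twisting(read_structure("2LAO.pdb"),
reference = read_structure("1LAF.pdb"))` reports the opening and twisting
angles of the open form relative to the closed form (about +38 and -26
degrees), and the corresponding test in the suite runs against them.
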