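Deposition-anchored checks look here for coordinate files that are too
large to ship with the package. To run them, download the following PDB
entries (mmCIF or PDB format) into this directory before installing:

    7CJS.cif   rice Lsi1 silicic-acid channel (two tetramers)
    1FX8.cif   E. coli glycerol facilitator GlpF
    5I32.cif   Arabidopsis AtTIP2;1
    6F7H.cif   human AQP10

e.g.  curl -O https://files.rcsb.org/download/7CJS.cif
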