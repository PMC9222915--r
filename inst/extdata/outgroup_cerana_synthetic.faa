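>outgroup_cerana_synthetic constructed divergent HVR-like peptide (not a database sequence)
SSLSGKDIHGKYDGYKDYGNDYGKDYGNKYGKLQHYKGYIEQI
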