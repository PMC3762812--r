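>trna_3prime_synthetic 18-mer tRNA 3-prime end fixture (synthetic)
TGGCGCAGTCAGGTACCA
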