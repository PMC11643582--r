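Synthetic example survey (10 individuals) generated by the package
generator (seed 123) for demonstrating external-csv mode. Not real
survey data.
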