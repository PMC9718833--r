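Synthetic example data.

synthetic_coupling_{avet,gtp,inoue}.csv are SYNTHETIC G protein coupling
tables written for examples and tests. They imitate the three source
dialects (double-normalized Emax values for the BRET-style dataset;
primary/secondary/none categories for the curated and chimeric-assay
datasets) and the qualitative coupling patterns reported in the literature
for the named receptors, but every value is invented. Do not use them as
measurements.
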