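wavelength_nm,intensity
405.7,0.55
437,0.80
547.4,1.00
578.9,0.75
595.3,0.50
621.1,0.85
699.2,0.30
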