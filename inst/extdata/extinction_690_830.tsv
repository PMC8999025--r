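# Molar extinction coefficients of hemoglobin, units 1/(mM*cm),
# standard compendium values (Prahl/Cope tabulation).
wavelength_nm	hbo	hbr
690	0.276	2.0520
830	0.974	0.6930
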