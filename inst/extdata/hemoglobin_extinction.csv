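# Molar decadic extinction coefficients of hemoglobin, 1/(cm * mol/L).
# Literature-typical values at the two operating wavelengths, in the style of
# the compiled Gratzer/Kollias whole-blood spectra widely used in near-infrared
# spectroscopy software. Override via the `extinction` argument of
# compute_dot_jacobian() / mbll() if a different tabulation is preferred.
wavelength_nm,hbo,hb
750,518.0,1405.2
850,1058.0,691.3
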