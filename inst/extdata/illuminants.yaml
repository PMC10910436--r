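# Default illuminant registries: the six-LED set used with the
# physical-distance apparatus (10 cd/m^2) and the three AMOLED screen
# primaries plus their broadband mix (15 cd/m^2). Narrowband FWHMs for the
# screen primaries are measured values; LED FWHMs are realistic free
# parameters.
- {name: "441", peak_nm: 441, fwhm_nm: 18, luminance_cdm2: 10, broadband: false}
- {name: "460", peak_nm: 460, fwhm_nm: 22, luminance_cdm2: 10, broadband: false}
- {name: "527", peak_nm: 527, fwhm_nm: 30, luminance_cdm2: 10, broadband: false}
- {name: "588", peak_nm: 588, fwhm_nm: 15, luminance_cdm2: 10, broadband: false}
- {name: "661", peak_nm: 661, fwhm_nm: 20, luminance_cdm2: 10, broadband: false}
- {name: "D65", peak_nm: 560, fwhm_nm: 0, luminance_cdm2: 10, broadband: true}
- {name: "459", peak_nm: 459, fwhm_nm: 20, luminance_cdm2: 15, broadband: false}
- {name: "528", peak_nm: 528, fwhm_nm: 25, luminance_cdm2: 15, broadband: false}
- {name: "610", peak_nm: 610, fwhm_nm: 28, luminance_cdm2: 15, broadband: false}
- {name: "RGB", peak_nm: 550, fwhm_nm: 0, luminance_cdm2: 15, broadband: true}
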