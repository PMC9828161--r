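# Visual system of the European Blackbird (Turdus merula), reconstructed
# from microspectrophotometry of this species (Hart et al. 2000,
# J. Comp. Physiol. A 186: 375-387): visual-pigment lambda-max of the four
# single-cone classes and the double cone, and relative cone proportions.
# Sensitivities are rebuilt from lambda-max with the A1 pigment template
# (oil-droplet filtering not applied; see package vignette). Weber
# fractions follow the common receptor-noise-limited default of 0.1 on the
# long-wave reference cone; illuminant is ideal (flat), which cancels in
# log-ratio receptor signals.
receptors:
  - name: uvs
    lambda_max: 373   # nm, SWS1 single cone
    abundance: 1.00
  - name: sws
    lambda_max: 454   # nm, SWS2 single cone
    abundance: 1.78
  - name: mws
    lambda_max: 504   # nm, RH2 single cone
    abundance: 2.21
  - name: lws
    lambda_max: 557   # nm, LWS single cone
    abundance: 1.96
weber_reference: lws
weber_fraction: 0.1
achromatic:
  lambda_max: 557     # double cone, luminance channel
  weber: 0.1
illuminant: ideal
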