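# Example simulation config for `fpmtools simulate --config ...`
wells: [A1, B2]        # well IDs to simulate
tile_um: 25.6          # tile side in um (64 raw pixels)
n_spoke_pairs: 16      # Siemens-star spoke pairs per well
m: 8                   # source separation of the illumination batch
surface_shape: flat    # or spherical_cap
wavelength_nm: 533
na_obj: 0.23
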