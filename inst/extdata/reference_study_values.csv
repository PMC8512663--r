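quantity,value
oz_peak_to_peak_off_uv,30
oz_peak_to_peak_on_uv,120
fz_zero_crossings_off,22.12
fz_zero_crossings_sma,20.84
oz_rms_off_uv,5.29
oz_rms_on_uv,25.40
oz_zero_crossings_off,26.55
oz_zero_crossings_on,41.90
oz_hfd_off,1.054
oz_hfd_on,1.065
chance_level_30_trials_pct,67
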