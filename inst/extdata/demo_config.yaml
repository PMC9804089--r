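# Demo simulation config: a reduced study that runs in a couple of
# minutes. Omitted keys fall back to the documented defaults of
# simulation_config(), which reproduce the full study design
# (31 adults / 31 controls / 20 patients at 50 Hz, 25 s + 30 s phases).
n_adults: 8
n_controls: 8
n_patients: 8
seed: 1
sampling_rate: 25
duration: 15
accommodation_duration: 5
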