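# Sleeper-phenotype defaults for the synthetic wearable-data generator.
# Clock times are local "HH:MM" (24-h); SDs in minutes; temperatures in degC;
# acrophase in minutes after local midnight.
#
# regular_young : healthy younger adult, quiet consolidated sleep
# regular_old   : healthy older adult, periodic in-sleep limb movements
#                 (brief bursts about every 30 s over a 2.5-h window after
#                 sleep onset)
# fragmented_oawd: older adult living with dementia; fragmented sleep
#                 (static episodes each under 30 min separated by movement),
#                 daytime naps, mostly unfilled observation sheets
regular_young:
  mean_onset: "00:32"
  mean_offset: "07:55"
  onset_sd: 53
  offset_sd: 54
  sleep_temp: 34.98
  wake_temp: 32.50
  cosinor_mesor: 33.34
  cosinor_amplitude: 1.72
  cosinor_acrophase: 246
  temp_noise_sd: 0.5
  movement_mode: quiet
  fragment_episode_max: 30
  nap_rate: 0.0
  shower_rate: 0.7
  sheet_fill_fraction: 1.0
regular_old:
  mean_onset: "23:49"
  mean_offset: "07:31"
  onset_sd: 61
  offset_sd: 78
  sleep_temp: 34.97
  wake_temp: 32.93
  cosinor_mesor: 33.65
  cosinor_amplitude: 1.45
  cosinor_acrophase: 183
  temp_noise_sd: 0.5
  movement_mode: periodic_30s
  fragment_episode_max: 30
  nap_rate: 0.0
  shower_rate: 0.7
  sheet_fill_fraction: 1.0
fragmented_oawd:
  mean_onset: "21:37"
  mean_offset: "07:05"
  onset_sd: 105
  offset_sd: 40
  sleep_temp: 34.66
  wake_temp: 33.40
  cosinor_mesor: 33.90
  cosinor_amplitude: 0.93
  cosinor_acrophase: 44
  temp_noise_sd: 0.5
  movement_mode: fragmented
  fragment_episode_max: 30
  nap_rate: 1.0
  shower_rate: 0.7
  sheet_fill_fraction: 0.4
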