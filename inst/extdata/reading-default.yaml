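sentences:
- - flee
  - wait
  - feed
  - wait
- - wait
  - flee
  - flee
  - feed
- - wait
  - wait
  - feed
  - feed
- - flee
  - wait
  - feed
  - flee
- - flee
  - wait
  - wait
  - flee
- - flee
  - flee
  - wait
  - wait
wrong_log_pref: -4.0
right_log_pref: 1.0
vflip_prior:
- 0.875
- 0.125
hflip_prior:
- 0.5
- 0.5
violation: none
global_factor: 8.0
exemplar_sentence: 1
exemplar_vflip_word: 2
threshold_nats: 0.001953125
kappa: 0.25
n_iterations: 16
ms_per_iteration: 16.0
band_hz:
- 4.0
- 32.0
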