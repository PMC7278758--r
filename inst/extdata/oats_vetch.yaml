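# Stall-fed crossbred dairy cows fed oats-vetch hay ad libitum,
# simulated for five monthly steps from calving.  Animal and diet values
# are the published trial means; birth weight and the mature body-weight
# envelope (min_mature_weight, max_attainable_weight) are calibrated
# model settings, not trial measurements -- override them here if better
# breed data are available.
breed:
  name: crossbred dairy cow (Ethiopia)
  species_class: crossbred
  sex: female
  birth_weight: 32.0
  max_attainable_weight: 630.0
  min_mature_weight: 38.0
  gompertz_mu0: 0.015
  max_daily_gain: 1.2
  peak_milk_yield: 20.0
  peak_month: 2.0
  lactation_length: 10.0
  milk_fat: 46.6
  milk_protein: 31.2
  kl: 0.6
animal:
  age: 5.2
  body_weight: 432.0
  lactation_month: 1.0
  gestation_day: 0.0
  parity: 3.0
ration:
  dm: 888.0
  me: 9.6
  ndf: 0.61
  cp: 87.5
  contains_concentrate: no
  offered_dm: .inf
simulation:
  n_steps: 5
  horizontal_distance: 0.0
  vertical_distance: 0.0
  days_per_step: 30.4
  milk_condition_exponent: 0.16
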