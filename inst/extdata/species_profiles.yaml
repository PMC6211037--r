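# Species profiles for the synthetic duet generator.
#
# One entry per studied titi species.  Numeric targets are the published
# per-species statistics the generator is calibrated to reproduce:
#   dominant_frequency_hz  dominant frequency of the combined duet signal
#   sequence_duration_s    mean duet sequence duration (male-pant marker to marker)
#   pant_rate_cps          pant call rate, calls/s
#   pump_rate_cps          pump (or rhythmic-phrase) call rate, calls/s
#   bellows_min/max        bellows per male bellow phrase
#   n_groups               family groups sampled per species in the study design
# `lineage` is the published taxonomic placement; `acoustic_lineage` is the
# placement suggested by the duet phenotype (they differ for urubambensis,
# whose duet follows the moloch pattern, and for oenanthe, whose duet is a
# vocal phenotype of its own).
default:
  sex_offset_hz: 100
  jitter_cv: 0.05
species:
  - species: donacophilus
    lineage: donacophilus
    acoustic_lineage: donacophilus
    pattern: donacophilus
    dominant_frequency_hz: 1202.8
    sequence_duration_s: 4.83
    pant_rate_cps: 3.33
    pump_rate_cps: 4.1
    pump_present: false
    n_groups: 7
  - species: pallescens
    lineage: donacophilus
    acoustic_lineage: donacophilus
    pattern: donacophilus
    dominant_frequency_hz: 1098.2
    sequence_duration_s: 3.98
    pant_rate_cps: 3.52
    pump_rate_cps: 4.1
    pump_present: false
    n_groups: 2
  - species: olallae
    lineage: donacophilus
    acoustic_lineage: donacophilus
    pattern: donacophilus
    dominant_frequency_hz: 1216.6
    sequence_duration_s: 5.49
    pant_rate_cps: 3.53
    pump_rate_cps: 4.1
    pump_present: false
    n_groups: 2
  - species: modestus
    lineage: donacophilus
    acoustic_lineage: donacophilus
    pattern: donacophilus
    dominant_frequency_hz: 947.5
    sequence_duration_s: 6.34
    pant_rate_cps: 3.16
    pump_rate_cps: 4.1
    pump_present: false
    n_groups: 1
  - species: oenanthe
    lineage: donacophilus
    acoustic_lineage: oenanthe
    pattern: oenanthe
    dominant_frequency_hz: 1464.2
    sequence_duration_s: 20.85
    pant_rate_cps: 4.49
    pump_present: false
    n_groups: 1
  - species: urubambensis
    lineage: donacophilus
    acoustic_lineage: moloch
    pattern: moloch
    dominant_frequency_hz: 839.8
    sequence_duration_s: 13.89
    pant_rate_cps: 3.11
    pump_rate_cps: 4.18
    pump_present: true
    bellows_min: 9
    bellows_max: 11
    n_groups: 1
  - species: discolor
    lineage: moloch
    acoustic_lineage: moloch
    pattern: moloch
    dominant_frequency_hz: 1003.99
    sequence_duration_s: 15.04
    pant_rate_cps: 3.35
    pump_rate_cps: 4.14
    pump_present: true
    bellows_min: 11
    bellows_max: 12
    n_groups: 8
  - species: toppini
    lineage: moloch
    acoustic_lineage: moloch
    pattern: moloch
    dominant_frequency_hz: 978.22
    sequence_duration_s: 13.61
    pant_rate_cps: 2.88
    pump_rate_cps: 4.26
    pump_present: true
    bellows_min: 8
    bellows_max: 10
    n_groups: 7
  - species: aureipalatii
    lineage: moloch
    acoustic_lineage: moloch
    pattern: moloch
    dominant_frequency_hz: 1012.1
    sequence_duration_s: 11.16
    pant_rate_cps: 3.62
    pump_rate_cps: 4.89
    pump_present: true
    bellows_min: 7
    bellows_max: 9
    n_groups: 1
  - species: lucifer
    lineage: torquatus
    acoustic_lineage: torquatus
    pattern: torquatus
    dominant_frequency_hz: 671.1
    sequence_duration_s: 6.39
    pant_rate_cps: 2.05
    pump_present: false
    n_groups: 6
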