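# Default labeling-function thresholds, in sex-normalized primitive units.
# Calibrated once from quantiles of a seeded phantom development cohort
# (n = 400, prevalence 0.06) mirroring how thresholds would be set from the
# distributional statistics of an expert-labeled development set.
labeling_functions:
  LF_Area:
    feature: area
    input_primitives: [area]
    low: 0.8099
    high: 1.1107
    low_vote: 1
    high_vote: -1
  LF_Perimeter:
    feature: perimeter
    input_primitives: [perimeter]
    high: 1.0790
    high_vote: 1
  LF_Eccentricity:
    feature: eccentricity
    input_primitives: [eccentricity]
    low: 0.9697
    high: 1.3141
    low_vote: -1
    high_vote: 1
  LF_Intensity:
    feature: intensity
    input_primitives: [intensity]
    high: 1.4760
    high_vote: -1
  LF_Ratio:
    feature: ratio
    input_primitives: [area, perimeter]
    low: 1.0322
    high: 1.1092
    low_vote: 1
    high_vote: -1
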