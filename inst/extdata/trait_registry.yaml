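- trait: residence
  family: demographic
  scale_min: 1.0
  scale_max: 4.0
  integer_valued: yes
  description: 'size of residence: metropolis (1) to village (4)'
- trait: education
  family: demographic
  scale_min: 1.0
  scale_max: 4.0
  integer_valued: yes
  description: 'education level: elementary (1) to university (4)'
- trait: age_difference
  family: demographic
  scale_min: -360.0
  scale_max: 360.0
  integer_valued: no
  description: partner minus respondent age in months; negative = woman older
- trait: weight
  family: physical
  scale_min: 40.0
  scale_max: 140.0
  integer_valued: no
  description: body weight in kilograms
- trait: height
  family: physical
  scale_min: 150.0
  scale_max: 220.0
  integer_valued: no
  description: body height in centimetres
- trait: attractiveness
  family: physical
  scale_min: 1.0
  scale_max: 7.0
  integer_valued: yes
  description: overall attractiveness, 7-point Likert
- trait: masculinity
  family: physical
  scale_min: 1.0
  scale_max: 7.0
  integer_valued: yes
  description: overall masculinity, 7-point Likert
- trait: eye_color
  family: physical
  scale_min: 1.0
  scale_max: 5.0
  integer_valued: yes
  description: 'eye colour image scale: grey, blue, green, brown, black'
- trait: hair_color
  family: physical
  scale_min: 1.0
  scale_max: 9.0
  integer_valued: yes
  description: 'hair colour image scale: light blond (1) to black (9)'
- trait: facial_masculinity
  family: physical
  scale_min: 1.0
  scale_max: 5.0
  integer_valued: yes
  description: facial masculinity image scale, low to high
- trait: beardedness
  family: physical
  scale_min: 1.0
  scale_max: 4.0
  integer_valued: yes
  description: 'beardedness image scale: clean shaven to full beard'
- trait: muscularity
  family: physical
  scale_min: 1.0
  scale_max: 6.0
  integer_valued: yes
  description: muscularity image scale, low to high
- trait: bmi
  family: physical
  scale_min: 1.0
  scale_max: 6.0
  integer_valued: yes
  description: body-mass-index image scale, low to high
- trait: relative_height
  family: physical
  scale_min: 1.0
  scale_max: 6.0
  integer_valued: yes
  description: 'relative height image scale: man much taller to woman taller'
- trait: hirsuteness
  family: physical
  scale_min: 1.0
  scale_max: 5.0
  integer_valued: yes
  description: body hair image scale, low to high
- trait: leg_to_body_ratio
  family: physical
  scale_min: 1.0
  scale_max: 5.0
  integer_valued: yes
  description: leg-to-body-ratio image scale, short to long legs
- trait: extraversion
  family: personality
  scale_min: 2.0
  scale_max: 14.0
  integer_valued: yes
  description: TIPI extraversion domain score
- trait: agreeableness
  family: personality
  scale_min: 2.0
  scale_max: 14.0
  integer_valued: yes
  description: TIPI agreeableness domain score
- trait: conscientiousness
  family: personality
  scale_min: 2.0
  scale_max: 14.0
  integer_valued: yes
  description: TIPI conscientiousness domain score
- trait: emotional_stability
  family: personality
  scale_min: 2.0
  scale_max: 14.0
  integer_valued: yes
  description: TIPI emotional stability domain score
- trait: openness
  family: personality
  scale_min: 2.0
  scale_max: 14.0
  integer_valued: yes
  description: TIPI openness domain score
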