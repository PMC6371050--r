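trait,observed_delta,expected_delta,expected_sd,effect_pct,icc_pct,pearson_r
residence,0.72,1.23,0.03,19.48,43.58,0.42
education,0.72,0.87,0.02,7.17,19.24,0.18
weight,8.82,11.31,0.24,16.21,33.77,0.31
height,6.3,7.42,0.16,11.28,24.56,0.22
age_difference,44.05,49.44,1.13,10.49,13.97,0.14
attractiveness,1.23,1.44,0.03,8.28,16.49,0.19
masculinity,1.26,1.4,0.03,5.51,9.71,0.11
eye_color,1.28,1.35,0.03,2.76,4.31,0.05
hair_color,2.54,2.74,0.07,4.81,10.17,0.12
facial_masculinity,1.66,1.46,0.04,0.07,0,-0.05
beardedness,0.67,0.67,0.02,0.07,6.83,0.08
muscularity,1.01,1.03,0.03,1.27,3.43,0.05
bmi,1.25,1.35,0.03,4.23,11.87,0.17
relative_height,1.18,1.5,0.04,11.99,30.58,0.34
hirsuteness,1.41,1.48,0.04,2.56,10.31,0.12
leg_to_body_ratio,1.21,1.35,0.03,5.93,13.52,0.12
extraversion,3.12,3.36,0.08,5.25,9.32,0.12
agreeableness,2.94,3.14,0.07,5.07,3.55,0.06
conscientiousness,3.68,3.92,0.09,4.68,5.08,0.09
emotional_stability,3.29,3.57,0.08,5.84,8.1,0.12
openness,2.91,3.21,0.07,6.94,9.27,0.11
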