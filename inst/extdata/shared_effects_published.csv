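trait,residence,education,weight,height,age_difference,attractiveness,masculinity,eye_color,hair_color,facial_masculinity,beardedness,muscularity,bmi,relative_height,hirsuteness,leg_to_body_ratio,extraversion,agreeableness,conscientiousness,emotional_stability,openness
residence,19.4,-0.26,-0.02,-0.06,-0.01,-0.03,-0.04,-0.07,-0.08,-0.04,-0.04,-0.03,-0.01,-0.02,0.02,-0.07,-0.01,0.03,0,0.01,-0.11
education,3.2,7.1,0.06,0.12,-0.07,0.04,0.05,0,0.04,0.01,0.02,0.03,0.04,-0.03,0.09,0.1,-0.07,0.13,0.27,0.16,0.1
weight,5.3,1.8,16.1,0.48,0.17,-0.02,0.26,-0.01,0.05,0.09,0.16,0.24,0.59,-0.25,0.27,0.02,0.04,-0.02,0.08,0.05,0.03
height,4,1.6,5,11.2,0.01,0.08,0.14,-0.03,0.02,0.19,0.05,0.07,0.04,-0.58,0.03,0.44,0.03,0.03,0.06,0.09,0.04
age_difference,3.5,1.5,3.3,2.5,10.3,-0.03,0.13,-0.01,0.08,0.15,0.14,0.07,0.18,0.06,0.14,-0.04,0.05,-0.03,0.03,-0.01,-0.01
attractiveness,2.7,1.4,2.5,2.1,1.7,8.3,0.45,0.02,0.09,0.19,0.09,0.28,-0.13,-0.05,0,0.07,0.19,0.17,0.1,0.18,0.19
masculinity,1.8,0.8,2.2,1.3,1.4,2.1,5.4,0.01,0.05,0.28,0.16,0.5,0.18,-0.1,0.18,-0.04,0.16,0.11,0.13,0.19,0.18
eye_color,1.1,0.3,0.7,0.6,0.6,0.4,0.2,2.7,0.39,0.03,0.04,-0.03,-0.02,-0.01,0.04,-0.03,0.03,0,-0.07,-0.03,0
hair_color,1.2,0.7,1,0.9,0.3,0.7,0.2,0.6,4.7,0.08,0.15,0.03,0.02,0.01,0.17,0.01,0.02,-0.01,-0.03,-0.02,0.02
facial_masculinity,0,0,0,0,0.1,0,0,0,0,0,0.19,0.31,-0.08,-0.12,0.16,0.15,0.04,-0.02,0,0.06,0.06
beardedness,0,0,0,0,0,0,0,0,0,0,0,0.13,0.14,-0.03,0.34,-0.01,0.07,0.06,0.02,0.08,0.12
muscularity,0.4,0.1,0.6,0.2,0.1,0.5,0.5,0.1,0.3,0,0,1.2,0.19,0.01,0.17,-0.08,0.09,0.1,0.12,0.15,0.13
bmi,0.6,0.1,1.7,0.3,0.2,0.5,0.6,0,0.1,0,0,0.4,4.2,0.01,0.3,-0.25,0.02,-0.01,0.08,0,-0.01
relative_height,4.1,1.4,3.7,4.9,2.8,2.3,1.2,0.6,0.8,0,0,0.3,0.4,11.9,0.01,-0.39,0,-0.02,-0.05,-0.06,0
hirsuteness,0.9,0.2,1,0.3,0.5,0.4,0.4,0,0.1,0,0,0.2,0.4,0.4,2.4,-0.1,0.01,0.03,0.08,0.01,0.03
leg_to_body_ratio,2,0.7,1.6,2.6,1.3,1.1,0.8,0.1,0.3,0,0,0.2,0.4,2.4,0.5,5.8,-0.05,0.02,0.03,0.04,0.02
extraversion,1.9,0.7,1.7,1.3,0.9,1.2,0.5,0.3,0.5,0,0,0.1,0.2,1.2,0.4,0.6,5.1,0.09,-0.09,0.17,0.38
agreeableness,1.8,0.5,1.6,0.7,0.2,0.9,0.9,0.1,0.2,0,0,0.2,0.2,0.5,0.4,0.5,1,5,0.33,0.48,0.22
conscientiousness,1.7,0.7,1,0.8,0.7,0.9,0.9,0.1,0.1,0,0,0,0,0.6,0.3,0.3,0.9,1.2,4.6,0.38,0.08
emotional_stability,2.2,0.9,2,1.4,1,1.1,0.8,0.2,0.3,0,0,0.3,0.3,0.9,0.5,0.5,1.2,2,1.3,5.8,0.19
openness,2.5,1,1.6,1.2,1.2,1.3,0.8,0.2,0.5,0,0,0.3,0.3,1.4,0.3,0.4,1.6,1.2,1,1.5,6.9
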