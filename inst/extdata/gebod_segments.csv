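name,mass_kg,Ixx_kgmm2,Iyy_kgmm2,Izz_kgmm2
Head,4.929,2.98E+04,2.61E+04,1.54E+04
Left_Foot,2.076,9.68E+03,8.58E+03,3.00E+03
Left_Hand,0.407,4.62E+02,4.62E+02,2.30E+02
Left_Lower_Arm,1.398,9.17E+03,9.17E+03,9.74E+02
Left_Lower_Leg,3.465,4.87E+04,4.87E+04,4.08E+03
Left_Scapula,1.773,5.55E+03,5.55E+03,2.51E+03
Left_Upper_Arm,1.662,1.19E+04,1.19E+04,1.32E+03
Left_Upper_Leg,5.807,8.45E+04,8.45E+04,1.14E+04
Lower_Torso,7.496,5.75E+04,5.47E+04,2.99E+04
Neck,1.208,2.39E+03,2.39E+03,1.58E+03
Right_Foot,2.076,9.68E+03,8.58E+03,3.00E+03
Right_Hand,0.407,4.62E+02,4.62E+02,2.30E+02
Right_Lower_Arm,1.398,9.17E+03,9.17E+03,9.74E+02
Right_Lower_Leg,3.465,4.87E+04,4.87E+04,4.08E+03
Right_Scapula,1.773,5.55E+03,5.55E+03,2.51E+03
Right_Upper_Arm,1.662,1.19E+04,1.19E+04,1.32E+03
Right_Upper_Leg,5.807,8.45E+04,8.45E+04,1.14E+04
Upper_Torso,12.746,1.32E+05,1.05E+05,8.82E+04
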