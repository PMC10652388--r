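dimension,value_mm
Ankle circumference,211.0435825
Ankle height outside,140.4683459
Armpit height,1323.854381
Biceps circumference,280.3974815
Buttock depth,209.271062
Calf circumference,341.0846869
Chest breadth,301.1401516
Chest depth,218.5973197
Elbow circumference,299.4991444
Foot breadth,95.97301467
Foot length,270.7387811
Forearm circumference,262.5570257
Forearm/head length,499.5140956
Head breadth,153.6571
Head length,197.4350064
Head to chin height,228.946798
Hip breadth standing,331.105377
Knee circumference,367.3743512
Neck circumference,360.1179666
Knee height seated,562.4855635
Seated height,938.988042
Shoulder breadth,479.1378574
Shoulder height,1468.070504
Shoulder-to-elbow length,365.0986821
Standing height,1800
Thigh circumference,519.2038789
Upper leg circumference,361.9016057
Waist breadth,275.0127284
Waist depth,191.4139039
Waist height,1089.26063
Ankle circumference,168.8972904
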