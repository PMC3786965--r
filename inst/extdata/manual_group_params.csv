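behavior,group,strain,mean_freq,sem_freq,mean_dur,sem_dur
Writhe,ASa,C57,0,0,,
Writhe,ASa,C3H,0.8,0.5,,
Writhe,ABupL,C57,0,0,,
Writhe,ABupL,C3H,0,0,,
Writhe,ABupH,C57,0,0,,
Writhe,ABupH,C3H,1,0.4,,
Writhe,VSa,C57,3.3,0.85,,
Writhe,VSa,C3H,3.3,1.3,,
Writhe,VBupL,C57,2.5,0.65,,
Writhe,VBupL,C3H,4.3,1.9,,
Writhe,VBupH,C57,0.8,0.5,,
Writhe,VBupH,C3H,3.5,2,,
Press2,ASa,C57,0,0,,
Press2,ASa,C3H,0.5,0.3,,
Press2,ABupL,C57,0.3,0.25,,
Press2,ABupL,C3H,0.3,0.25,,
Press2,ABupH,C57,0,0,,
Press2,ABupH,C3H,0.3,0.25,,
Press2,VSa,C57,0.5,0.3,,
Press2,VSa,C3H,1,0,,
Press2,VBupL,C57,0.5,0.3,,
Press2,VBupL,C3H,2.3,0.25,,
Press2,VBupH,C57,0,0,,
Press2,VBupH,C3H,2.8,1.8,,
Rear Leg Lift,ASa,C57,0,0,,
Rear Leg Lift,ASa,C3H,0.5,0.3,,
Rear Leg Lift,ABupL,C57,0.5,0.5,,
Rear Leg Lift,ABupL,C3H,0.5,0.3,,
Rear Leg Lift,ABupH,C57,0.5,0.5,,
Rear Leg Lift,ABupH,C3H,0,0,,
Rear Leg Lift,VSa,C57,1.3,0.25,,
Rear Leg Lift,VSa,C3H,4.3,2,,
Rear Leg Lift,VBupL,C57,3,1.2,,
Rear Leg Lift,VBupL,C3H,3.3,0.75,,
Rear Leg Lift,VBupH,C57,0.3,0.25,,
Rear Leg Lift,VBupH,C3H,0.8,0.75,,
Lick Wound,ASa,C57,2.8,1.2,4.5,1.6
Lick Wound,ASa,C3H,0.3,0.25,4.7,4.7
Lick Wound,ABupL,C57,0.5,0.5,0.9,0.85
Lick Wound,ABupL,C3H,1.3,0.5,2.6,1.65
Lick Wound,ABupH,C57,1,0.7,1.4,1.1
Lick Wound,ABupH,C3H,0,0,0,0
Lick Wound,VSa,C57,17,2.3,126.7,7
Lick Wound,VSa,C3H,7.8,1,44.4,17
Lick Wound,VBupL,C57,19.5,4.1,103.2,30
Lick Wound,VBupL,C3H,4,1.3,13.7,8.7
Lick Wound,VBupH,C57,2.5,0.25,8.6,8.5
Lick Wound,VBupH,C3H,0.5,0.3,1.7,1.1
Scratch Wound,ASa,C57,0,0,0,0
Scratch Wound,ASa,C3H,0.5,0.5,0.6,0.65
Scratch Wound,ABupL,C57,0,0,0,0
Scratch Wound,ABupL,C3H,0.3,0.25,0.1,0.1
Scratch Wound,ABupH,C57,0,0,0,0
Scratch Wound,ABupH,C3H,0,0,0,0
Scratch Wound,VSa,C57,0.3,0.25,0.5,0.5
Scratch Wound,VSa,C3H,6.5,2.7,10,2
Scratch Wound,VBupL,C57,0.3,0.25,0.4,0.4
Scratch Wound,VBupL,C3H,7,2.3,11.2,4
Scratch Wound,VBupH,C57,0,0,0,0
Scratch Wound,VBupH,C3H,2,2,0.6,0.55
Abnormal Walk,ASa,C57,1,0.4,2.6,1.35
Abnormal Walk,ASa,C3H,17,10.5,24.1,12
Abnormal Walk,ABupL,C57,1.5,0.3,3.4,0.95
Abnormal Walk,ABupL,C3H,4.8,2.7,9.8,5.5
Abnormal Walk,ABupH,C57,20.5,17,67.5,55
Abnormal Walk,ABupH,C3H,31.8,9.5,73.9,22.5
Abnormal Walk,VSa,C57,32,6,91.6,18
Abnormal Walk,VSa,C3H,39.8,6.5,97.6,19
Abnormal Walk,VBupL,C57,47.5,2.2,143.4,19
Abnormal Walk,VBupL,C3H,51.5,5.6,139.4,27
Abnormal Walk,VBupH,C57,46.3,5,280.9,11
Abnormal Walk,VBupH,C3H,51.3,11.5,160.7,45
High Rear,ASa,C57,21.5,7.5,35.6,12
High Rear,ASa,C3H,31,3.8,49.2,8
High Rear,ABupL,C57,23.5,2.6,32.9,5
High Rear,ABupL,C3H,23,1.2,35.2,4.1
High Rear,ABupH,C57,3.5,1.8,3.8,2.3
High Rear,ABupH,C3H,1,0.7,1.1,0.8
High Rear,VSa,C57,3.3,1.8,3.9,1.9
High Rear,VSa,C3H,8.8,2.1,11,2.9
High Rear,VBupL,C57,0.8,0.25,1.1,0.4
High Rear,VBupL,C3H,0.8,0.5,0.9,0.55
High Rear,VBupH,C57,0.5,0.5,0.4,0.45
High Rear,VBupH,C3H,2,1.2,1.9,1.1
Lick Head,ASa,C57,12.5,0.5,18.4,4.5
Lick Head,ASa,C3H,9.3,2.5,15.4,3.5
Lick Head,ABupL,C57,8,1.2,9.5,1.3
Lick Head,ABupL,C3H,5,0.7,10.2,1.1
Lick Head,ABupH,C57,8,2.4,12.3,2.25
Lick Head,ABupH,C3H,7.8,1.6,25.5,7
Lick Head,VSa,C57,6.3,1.6,10.4,2
Lick Head,VSa,C3H,1.8,0.5,4.3,0.65
Lick Head,VBupL,C57,6,2,8.4,2
Lick Head,VBupL,C3H,1.3,0.25,6.7,2.3
Lick Head,VBupH,C57,3,0.7,5.3,0.85
Lick Head,VBupH,C3H,2.5,0.3,8.8,1.1
Scratch Head,ASa,C57,1,0.4,0.6,0.25
Scratch Head,ASa,C3H,2.3,0.85,1.1,0.4
Scratch Head,ABupL,C57,1.3,0.5,0.9,0.3
Scratch Head,ABupL,C3H,0,0,0,0
Scratch Head,ABupH,C57,0.5,0.5,0.4,0.35
Scratch Head,ABupH,C3H,0,0,0,0
Scratch Head,VSa,C57,0.8,0.5,0.6,0.45
Scratch Head,VSa,C3H,0,0,0,0
Scratch Head,VBupL,C57,0.3,0.25,0.4,0.45
Scratch Head,VBupL,C3H,0,0,0,0
Scratch Head,VBupH,C57,0.3,0.25,0.5,0.45
Scratch Head,VBupH,C3H,0,0,0,0
Scratch Other,ASa,C57,0.8,0.5,0.5,0.3
Scratch Other,ASa,C3H,1,0,0.8,0.15
Scratch Other,ABupL,C57,0.8,0.5,0.7,0.4
Scratch Other,ABupL,C3H,0.3,0.25,0.3,0.25
Scratch Other,ABupH,C57,0.3,0.25,0.2,0.16
Scratch Other,ABupH,C3H,0,0,0,0
Scratch Other,VSa,C57,0.3,0.25,0.3,0.35
Scratch Other,VSa,C3H,0.3,0.25,0.3,0.35
Scratch Other,VBupL,C57,0.3,0.25,0.3,0.35
Scratch Other,VBupL,C3H,0,0,0,0
Scratch Other,VBupH,C57,0,0,0,0
Scratch Other,VBupH,C3H,0,0,0,0
Dig,ASa,C57,33.8,8,31.5,7.5
Dig,ASa,C3H,16.5,3,14.2,3.8
Dig,ABupL,C57,30.3,10,24.6,10
Dig,ABupL,C3H,26.3,9.5,23.4,9
Dig,ABupH,C57,27.8,15.5,41.9,25.5
Dig,ABupH,C3H,1.8,1.2,1.3,1
Dig,VSa,C57,2.5,1.8,2.2,1.4
Dig,VSa,C3H,9.5,6.4,8.9,5.9
Dig,VBupL,C57,0.3,0.25,0.1,0.5
Dig,VBupL,C3H,0.3,0.25,0.3,0.25
Dig,VBupH,C57,0.5,0.5,0.2,0.2
Dig,VBupH,C3H,0,0,0,0
Normal Posture,ASa,C57,21.8,8.5,195,72.5
Normal Posture,ASa,C3H,9.5,5.5,43,25
Normal Posture,ABupL,C57,16,7,196,75
Normal Posture,ABupL,C3H,31.3,11,171,52
Normal Posture,ABupH,C57,3.8,1.9,249,62
Normal Posture,ABupH,C3H,5.3,2.3,187.6,6.5
Normal Posture,VSa,C57,0.5,0.3,7.7,4.9
Normal Posture,VSa,C3H,10.3,4.6,77,34
Normal Posture,VBupL,C57,0.3,0.25,4.9,4.9
Normal Posture,VBupL,C3H,3.5,0.72,234,80
Normal Posture,VBupH,C57,1,0.4,82.3,65
Normal Posture,VBupH,C3H,4.8,2.25,251,61.5
Walk Normal,ASa,C57,90,7,155,13.5
Walk Normal,ASa,C3H,72.8,8.5,105.3,8
Walk Normal,ABupL,C57,98.3,3.6,199.3,13
Walk Normal,ABupL,C3H,99.3,6.2,145.8,7
Walk Normal,ABupH,C57,61.3,20.2,162,57
Walk Normal,ABupH,C3H,32.8,13.1,97.9,47.6
Walk Normal,VSa,C57,12.8,4.7,24,9.3
Walk Normal,VSa,C3H,28.3,12,50,19
Walk Normal,VBupL,C57,1.8,0.65,5.2,2.7
Walk Normal,VBupL,C3H,9.5,8.5,20.5,16.2
Walk Normal,VBupH,C57,0.8,0.5,6.2,0.55
Walk Normal,VBupH,C3H,7,3.3,13.4,8
Stop,ASa,C57,92.5,7.5,139,16.5
Stop,ASa,C3H,98.5,3.3,190,7
Stop,ABupL,C57,94,6,118.4,14
Stop,ABupL,C3H,99.8,2.8,167.9,8
Stop,ABupH,C57,73.3,7.1,72.1,2.8
Stop,ABupH,C3H,73.3,8,154.6,25
Stop,VSa,C57,65.5,4.3,98,13.9
Stop,VSa,C3H,73.5,59,143,20
Stop,VBupL,C57,70.5,2.6,92,15
Stop,VBupL,C3H,67.3,0.65,167,22.5
Stop,VBupH,C57,49.8,9,58.4,10
Stop,VBupH,C3H,60,13.5,170,45
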