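behavior,modality,source
Writhe,frequency,manual
Press2,frequency,manual
Rear Leg Lift,frequency,manual
Lick Wound,both,manual
Scratch Wound,both,manual
Abnormal Walk,both,manual
High Rear,both,manual
Lick Head,both,manual
Scratch Head,both,manual
Scratch Other,both,manual
Dig,both,manual
Normal Posture,both,manual
Walk Normal,both,manual
Stop,both,manual
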