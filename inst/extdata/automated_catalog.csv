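behavior,modality,source
Jumping,frequency,automated
Come Down,frequency,automated
Rear Up,frequency,automated
Walk Left,frequency,automated
Walk Right,frequency,automated
Come Down From Partially Reared,frequency,automated
Come Down To Partially Reared,frequency,automated
Rear Up From Partially Reared,frequency,automated
Remain Low,frequency,automated
Remain Partially Reared,frequency,automated
Sniff,frequency,automated
Walk Slow,frequency,automated
Groom,frequency,automated
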