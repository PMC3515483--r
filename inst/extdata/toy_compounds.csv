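id,class,items
C1,,81;82;83;84
C2,,82;84
C3,,81;84
C4,,81;82;84;85
C5,,81;82;83;84;85
C6,,82;83;85
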