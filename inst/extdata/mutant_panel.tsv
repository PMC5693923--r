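name	parent	edits	observed
FBG-C mutant 1	FBG-C	sub:124K>A;sub:126R>A	reduced
FBG-C mutant 2	FBG-C	sub:128K>A;sub:130K>A	reduced
FBG-C mutant 3	FBG-C	sub:124K>A;sub:126R>A;sub:128K>A;sub:130K>A	inactive
FBG-C mutant 4	FBG-C	trunc:223	reduced
FBG-C mutant 5	FBG-C	sub:124K>A;sub:126R>A;sub:128K>A;sub:130K>A;trunc:223	inactive
FBG-C mutant 6	FBG-C	sub:157D>P;sub:160I>L;sub:162N>S	reduced
FBG-C mutant 7	FBG-C	sub:157D>P;sub:160I>L;sub:162N>S;sub:124K>A;sub:126R>A;sub:128K>A;sub:130K>A	inactive
FBG-X mutant 1	FBG-X	sub:124S>K;sub:126T>K;sub:128S>R	inactive
FBG-X mutant 2	FBG-X	replace:105-134:SWNDPLGEYWLGNDNIHLLKTRYKLKNQAT	reduced
FBG-X mutant 3	FBG-X	replace:105-134:SWNDPLGEYWLGNDNIHLLKTRYKLKNQAT;append:RRKRA	active
FBG-X mutant 4	FBG-X	replace:105-134:SWNDPLGEYWLGNDNIHLLKTRYKLKNQAT;append:RRKRA;sub:161P>D;sub:165L>I;sub:167S>N	active
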