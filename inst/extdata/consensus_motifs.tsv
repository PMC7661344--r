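# Degenerate consensus motifs (bracket notation; x = any base).
# motif1 is the published most specific consensus; motif1_rc_printed is
# the looser reverse-complement form as published (usable as a pattern
# in its own right; the strict algebraic reverse complement is
# reverse_complement(motif1)). Motifs 2-6 of the original six-motif set
# were shown only as figure images and must be supplied by the user.
motif_id	pattern
motif1	CCTC[AT][GC]CC[TA]CC[CT]
motif1_rc_printed	[GA][GA][GC][AT]GG[CG]xxAGG
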