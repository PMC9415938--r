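profile	feature	column
GAF	cys	85
GAF	adj	86
GAF	triad1	40
GAF	triad2	90
GAF	triad3	125
pbp	cys	84
pbp	motif_start	30
pbp	motif_end	34
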