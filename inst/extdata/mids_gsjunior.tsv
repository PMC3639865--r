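MID	Sequence
MID01	TAATCTAATA
MID02	GTGCAGGTTC
MID03	ATAACTCGGC
MID04	TCATCGAGTC
MID05	CGTAGATCGT
MID06	AGTCAGCTAC
MID07	CCAACTACGG
MID08	AAACGTTGCA
MID09	CAAGCTGGGG
MID10	ACTCCGTACG
MID11	AGTCGTGAGT
MID12	AAGTTCGTAT
MID13	CTTGGAGAGA
MID14	TTCTTACCGA
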