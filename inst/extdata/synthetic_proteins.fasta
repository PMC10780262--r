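>synthA_gliadin_like synthetic test protein carrying the QPFPQPELPYP segment
MKTAYIAKQRQPFPQPELPYPGSLAVEHGQTWHE
>synthB_random synthetic random-composition protein
MSDLKVNTARHEWQGCFYIPLMNDSKTVAGHERC
>synthC_withX synthetic protein with one ambiguous residue
MKVLHEXTPGWQARNDSLIYFCEMKTHQ
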