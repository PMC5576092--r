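name	activity
Ntox50	nuclease
EndoU_bacteria	ribonuclease
cd13442	tRNase
Ntox34	nuclease
ADPRT_tox	ADP-ribosyl transferase
RelA_SpoT_tox	ppGpp synthetase
Peptidase_M35_tox	metallopeptidase
Colicin_D	ribonuclease
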