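colony,year,deployed,recovered,failed_nests,usable,trips
StPaul,2008,22,21,1,15,29
StPaul,2009,19,17,3,14,38
StPaul,2010,35,35,3,35,86
StGeorge,2008,23,21,2,11,15
StGeorge,2009,23,21,2,19,41
StGeorge,2010,39,39,5,39,101
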