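sample_id	species	bands
Oce.ref	Oxynotus centrina	510
Pgl.ref	Prionace glauca	400,110
Sca.ref	Scyliorhinus canicula	400,150
Mmu.ref	Mustelus mustelus	390,180,120
Xgl.cladeI	Xiphias gladius	240,220,170
Xgl.cladeII	Xiphias gladius	280,220,170
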