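species	seq_id	seq_length	fragments
Xiphias gladius	JN083387	682	145,270,220
Xiphias gladius	JN083389	682	145,270,220
Xiphias gladius	JN049558	682	145,270,220
Xiphias gladius	JF952886	652	145,265,220
Xiphias gladius	HQ024928	652	145,265,220
Xiphias gladius	HQ024927	652	145,265,220
Xiphias gladius	KR086931	652	145,265,220
Xiphias gladius	GU324195	652	145,265,220
Xiphias gladius	DQ107625	655	145,265,200
Xiphias gladius	DQ107623	655	145,265,220
Mustelus mustelus	JN641215	676	80,390,171
Mustelus mustelus	JN641214	679	80,390,169
Mustelus mustelus	JN641213	672	80,390,167
Mustelus mustelus	JN641212	666	80,390,156
Mustelus mustelus	JN641211	681	80,390,170
Mustelus mustelus	KJ768265	652	80,390,142
Mustelus mustelus	KJ768266	652	80,390,142
Mustelus mustelus	JN641208	656	75,390,156
Mustelus mustelus	JN641209	669	80,390,160
Mustelus mustelus	JN641210	664	80,390,160
Oxynotus centrina	KT307360	648	510,95
Oxynotus centrina	KT307361	620	480,95
Oxynotus centrina	KT307362	648	510,95
Oxynotus centrina	KT307363	648	510,95
Oxynotus centrina	KT307364	648	510,95
Oxynotus centrina	JF834320	672	505,100
Oxynotus centrina	KY176547	642	495,105
Oxynotus centrina	GU805137	637	500,95
Oxynotus centrina	GU805138	648	510,95
Prionace glauca	JN312505	652	85,405,70
Prionace glauca	JN312504	652	85,405,70
Prionace glauca	JN312503	652	85,405,70
Prionace glauca	KP193446	652	85,405,70
Prionace glauca	KP193455	652	85,405,70
Prionace glauca	KP193350	652	85,405,70
Prionace glauca	KP193339	652	85,405,70
Prionace glauca	KP193159	652	85,405,70
Prionace glauca	KC015834	652	85,405,70
Prionace glauca	KC015833	652	85,405,70
Scyliorhinus canicula	JN641243	675	85,400,100
Scyliorhinus canicula	JN641242	676	85,400,100
Scyliorhinus canicula	JN641241	652	70,400,100
Scyliorhinus canicula	JN641240	680	85,400,100
Scyliorhinus canicula	JN641239	675	85,400,100
Scyliorhinus canicula	JN641238	671	85,400,100
Scyliorhinus canicula	JN641237	680	85,400,100
Scyliorhinus canicula	JN641236	674	85,400,100
Scyliorhinus canicula	JN641234	672	85,400,100
Scyliorhinus canicula	JN641233	680	85,400,100
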