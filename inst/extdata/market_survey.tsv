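id	declared	matched	group
XIP1	Xiphias gladius	Xiphias gladius	reference
XIP2	Xiphias gladius	Xiphias gladius	reference
MUS1	Mustelus mustelus	Mustelus mustelus	reference
MUS2	Mustelus mustelus	Mustelus mustelus	reference
OXY1	Oxynotus centrina	Oxynotus centrina	reference
OXY2	Oxynotus centrina	Oxynotus centrina	reference
PRI1	Prionace glauca	Prionace glauca	reference
PRI2	Prionace glauca	Prionace glauca	reference
SCY1	Scyliorhinus canicula	Scyliorhinus canicula	reference
SCY2	Scyliorhinus canicula	Scyliorhinus canicula	reference
X1	Xiphias gladius	Xiphias gladius	2010
X2	Xiphias gladius	Xiphias gladius	2010
X3	Xiphias gladius	Xiphias gladius	2010
X4	Xiphias gladius	Xiphias gladius	2010
X5	Xiphias gladius	Xiphias gladius	2010
X6	Xiphias gladius	Xiphias gladius	2010
X7	Xiphias gladius	Xiphias gladius	2010
X8	Xiphias gladius	Xiphias gladius	2010
X9	Xiphias gladius	Xiphias gladius	2010
X10	Xiphias gladius	Xiphias gladius	2010
X11	Xiphias gladius	Xiphias gladius	2010
X12	Xiphias gladius	Xiphias gladius	2010
X13	Xiphias gladius	Prionace glauca	2010
X14	Xiphias gladius	Xiphias gladius	2010
X15	Xiphias gladius	Xiphias gladius	2010
Y1	Xiphias gladius	Xiphias gladius	2018
Y2	Xiphias gladius	Xiphias gladius	2018
Y3	Xiphias gladius	Xiphias gladius	2018
Y4	Xiphias gladius	Xiphias gladius	2018
Y5	Xiphias gladius	Xiphias gladius	2018
Y6	Xiphias gladius	Xiphias gladius	2018
Y7	Xiphias gladius	Mustelus mustelus	2018
Y8	Xiphias gladius	Xiphias gladius	2018
Y9	Xiphias gladius	Xiphias gladius	2018
Y10	Xiphias gladius	Oxynotus centrina	2018
Y11	Xiphias gladius	Xiphias gladius	2018
Y12	Xiphias gladius	Xiphias gladius	2018
Y13	Xiphias gladius	Xiphias gladius	2018
Y14	Xiphias gladius	Xiphias gladius	2018
Y15	Xiphias gladius	Prionace glauca	2018
Y16	Xiphias gladius	Xiphias gladius	2018
Y17	Xiphias gladius	Xiphias gladius	2018
Y18	Xiphias gladius	Xiphias gladius	2018
Y19	Xiphias gladius	Xiphias gladius	2018
Y20	Xiphias gladius	Xiphias gladius	2018
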