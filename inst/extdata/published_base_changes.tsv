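landrace	pair	count
indica_12	A/G	705908
indica_12	C/T	707496
indica_12	A/C	155310
indica_12	A/T	182882
indica_12	C/G	101541
indica_12	G/T	154639
indica_13	A/G	671815
indica_13	C/T	672959
indica_13	A/C	149265
indica_13	A/T	176243
indica_13	C/G	95523
indica_13	G/T	148304
indica_15	A/G	787002
indica_15	C/T	787976
indica_15	A/C	174014
indica_15	A/T	205343
indica_15	C/G	113736
indica_15	G/T	173286
japonica_11	A/G	255473
japonica_11	C/T	255542
japonica_11	A/C	59111
japonica_11	A/T	70949
japonica_11	C/G	39460
japonica_11	G/T	59011
japonica_14	A/G	236847
japonica_14	C/T	237620
japonica_14	A/C	55410
japonica_14	A/T	68165
japonica_14	C/G	37120
japonica_14	G/T	55639
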