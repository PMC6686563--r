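mirna_id	target_gene	confidence	direction
hsa-miR-1181	ID3	1.223	down
hsa-miR-1181	MBTPS1	0.454	down
hsa-miR-1181	SLC22A1	0.302	down
hsa-miR-1207-3p	BMX	0.896	down
hsa-miR-1207-3p	NOG	0.687	down
hsa-miR-1207-3p	MBTPS1	0.57	down
hsa-miR-1207-3p	SLC22A1	0.404	down
hsa-miR-1229-3p	ID3	0.555	down
hsa-miR-1246	NOG	0.359	up
hsa-miR-1246	MBTPS1	0.331	up
hsa-miR-1262	NOG	0.305	down
hsa-miR-138-2-3p	NOG	0.45	down
hsa-miR-1909-5p	NOG	0.445	down
hsa-miR-199a-5p	ID3	0.338	up
hsa-miR-29c-5p	MBTPS1	0.315	down
hsa-miR-3129-5p	ID3	0.395	down
hsa-miR-3180	MBTPS1	0.782	down
hsa-miR-3180	NOG	0.782	down
hsa-miR-3180	ID3	0.587	down
hsa-miR-3180	SLC22A1	0.556	down
hsa-miR-3180-3p	NOG	0.539	down
hsa-miR-3612	BMX	0.554	down
hsa-miR-3620-3p	ID3	0.786	down
hsa-miR-3657	MBTPS1	0.481	down
hsa-miR-371a-3p	NOG	0.703	down
hsa-miR-3960	MBTPS1	1.179	up
hsa-miR-3960	NOG	0.868	up
hsa-miR-3960	ID3	0.532	up
hsa-miR-3960	SLC22A1	0.439	up
hsa-miR-4259	NOG	0.349	down
hsa-miR-4436a	MBTPS1	0.601	down
hsa-miR-4436a	SLC22A1	0.339	down
hsa-miR-4436a	NOG	0.314	down
hsa-miR-4725-5p	ID3	0.405	up
hsa-miR-517a-3p	ID3	0.79	down
hsa-miR-517a-3p	SLC22A1	0.343	down
hsa-miR-517b-3p	ID3	0.79	down
hsa-miR-517b-3p	SLC22A1	0.343	down
hsa-miR-520a-3p	NOG	0.348	down
hsa-miR-532-5p	MBTPS1	0.323	down
hsa-miR-548n	NOG	0.362	down
hsa-miR-551b-3p	MBTPS1	0.302	down
hsa-miR-5587-3p	ID3	0.615	down
hsa-miR-5588-5p	ID3	0.392	down
hsa-miR-607	ID3	0.388	down
hsa-miR-615-5p	NOG	0.39	down
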