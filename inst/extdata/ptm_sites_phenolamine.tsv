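# Published post-translational-modification annotations of the A. tumida
# octopamine/tyramine receptors: motif string and 1-based position of the
# first residue, by PROSITE class (accessions as in ptm_patterns.dat).
# One printed CK2 entry for Atum_TAR2 ("REPE 341") does not satisfy the
# canonical CK2 pattern [ST]-x(2)-[DE] (presumed typographical error in the
# source table) and is omitted here.
receptor	pattern_id	motif	position
Atum_OctaR	PS00001	NATA	6
Atum_OctaR	PS00001	NSTL	171
Atum_OctaR	PS00001	NGSN	272
Atum_OctaR	PS00001	NSTT	275
Atum_OctaR	PS00001	NNSL	528
Atum_OctaR	PS00006	TDPE	20
Atum_OctaR	PS00006	TLQE	173
Atum_OctaR	PS00006	SSCD	371
Atum_OctaR	PS00006	TGRE	376
Atum_OctaR	PS00006	SSCD	387
Atum_OctaR	PS00006	SLGD	530
Atum_OctaR	PS00005	SSK	52
Atum_OctaR	PS00005	SHK	137
Atum_OctaR	PS00005	TTR	224
Atum_OctaR	PS00005	TTK	234
Atum_OctaR	PS00005	TLR	251
Atum_OctaR	PS00005	SGK	261
Atum_OctaR	PS00005	SNR	289
Atum_OctaR	PS00005	SHR	361
Atum_OctaR	PS00005	SSR	366
Atum_OctaR	PS00005	SRR	367
Atum_OctaR	PS00005	TGR	376
Atum_OctaR	PS00005	SRK	398
Atum_OctaR	PS00005	SRR	502
Atum_OctaR	PS00008	GSPHSN	267
Atum_OctaR	PS00008	GSNSTT	273
Atum_OctaR	PS00008	GIIVGG	424
Atum_OctaR	PS00008	GSDGSQ	505
Atum_OctaR	PS00008	GGDPSD	538
Atum_OctaR	PS00009	SGKR	261
Atum_OctaR	PS00009	MGKR	401
Atum_OctaR	PS00004	RRSS	363
Atum_OctaR	PS00004	RRSS	368
Atum_OctaR	PS00004	RRGS	503
Atum_Octb1R	PS00001	NETD	17
Atum_Octb1R	PS00001	NNTS	26
Atum_Octb1R	PS00001	NTSI	27
Atum_Octb1R	PS00001	NFSV	107
Atum_Octb1R	PS00001	NRTY	214
Atum_Octb1R	PS00001	NYSN	402
Atum_Octb1R	PS00001	NASS	405
Atum_Octb1R	PS00001	NISE	432
Atum_Octb1R	PS00006	TFSE	6
Atum_Octb1R	PS00006	STNE	15
Atum_Octb1R	PS00006	TDFD	19
Atum_Octb1R	PS00006	SVVE	109
Atum_Octb1R	PS00006	TTSD	194
Atum_Octb1R	PS00006	SENE	434
Atum_Octb1R	PS00005	SLR	276
Atum_Octb1R	PS00005	SSK	296
Atum_Octb1R	PS00005	TSK	385
Atum_Octb1R	PS00008	GISAGL	269
Atum_Octb1R	PS00008	GIIVSA	310
Atum_Octb2R	PS00001	NITV	3
Atum_Octb2R	PS00001	NVTN	7
Atum_Octb2R	PS00001	NATS	10
Atum_Octb2R	PS00001	NFSV	85
Atum_Octb2R	PS00001	NTTY	190
Atum_Octb2R	PS00001	NNTN	240
Atum_Octb2R	PS00001	NSTL	333
Atum_Octb2R	PS00006	TSTE	12
Atum_Octb2R	PS00006	TTEE	170
Atum_Octb2R	PS00006	TNGD	242
Atum_Octb2R	PS00006	TLHE	258
Atum_Octb2R	PS00006	SDLD	369
Atum_Octb2R	PS00005	TKK	141
Atum_Octb2R	PS00005	SSK	253
Atum_Octb2R	PS00005	SIR	380
Atum_Octb2R	PS00005	SDR	399
Atum_Octb2R	PS00008	GSSKTL	252
Atum_Octb2R	PS00008	GIIMGI	290
Atum_Octb2R	PS00004	RRPS	377
Atum_Octb2R	PS00004	RRCS	401
Atum_Octb3R	PS00001	NATL	19
Atum_Octb3R	PS00001	NRTN	24
Atum_Octb3R	PS00001	NVTN	27
Atum_Octb3R	PS00001	NASV	101
Atum_Octb3R	PS00006	TNIE	29
Atum_Octb3R	PS00006	TTNE	187
Atum_Octb3R	PS00006	SYRE	262
Atum_Octb3R	PS00006	SDGE	275
Atum_Octb3R	PS00005	THR	158
Atum_Octb3R	PS00005	SYR	262
Atum_Octb3R	PS00005	TIR	292
Atum_Octb3R	PS00005	SWR	299
Atum_Octb3R	PS00008	GQINGR	283
Atum_Octb3R	PS00008	GIIMGA	311
Atum_Octb3R	PS00009	NGRR	286
Atum_Octb3R	PS00004	RRST	288
Atum_TAR1	PS00001	NTSC	3
Atum_TAR1	PS00001	NFST	13
Atum_TAR1	PS00001	NQST	236
Atum_TAR1	PS00001	NNTH	286
Atum_TAR1	PS00006	SCVD	5
Atum_TAR1	PS00006	TPRE	241
Atum_TAR1	PS00006	SHED	295
Atum_TAR1	PS00006	SLTD	299
Atum_TAR1	PS00005	TYK	55
Atum_TAR1	PS00005	TLK	141
Atum_TAR1	PS00005	TKR	217
Atum_TAR1	PS00005	TPR	241
Atum_TAR1	PS00005	SRR	310
Atum_TAR1	PS00005	SPK	340
Atum_TAR1	PS00005	TKK	352
Atum_TAR1	PS00005	SRR	410
Atum_TAR1	PS00008	GNFSTI	12
Atum_TAR1	PS00008	GIDICK	97
Atum_TAR1	PS00008	GXGATK	348
Atum_TAR1	PS00008	GIIMGV	381
Atum_TAR1	PS00004	RRNS	311
Atum_TAR2	PS00001	NESS	3
Atum_TAR2	PS00001	NNTA	32
Atum_TAR2	PS00001	NKSS	327
Atum_TAR2	PS00001	NSTI	404
Atum_TAR2	PS00006	SSLE	7
Atum_TAR2	PS00006	SDVD	260
Atum_TAR2	PS00006	SECE	267
Atum_TAR2	PS00005	TTR	72
Atum_TAR2	PS00005	TRR	73
Atum_TAR2	PS00005	SRK	154
Atum_TAR2	PS00005	SKR	159
Atum_TAR2	PS00005	TRK	246
Atum_TAR2	PS00005	STK	249
Atum_TAR2	PS00005	SLR	312
Atum_TAR2	PS00005	SFR	363
Atum_TAR2	PS00005	TVK	441
Atum_TAR2	PS00005	TRR	448
Atum_TAR2	PS00008	GLTVAT	20
Atum_TAR2	PS00004	KRRS	156
Atum_TAR2	PS00004	RKST	247
Atum_TAR2	PS00004	RRET	365
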