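CC   Canonical PROSITE patterns for the six post-translational-modification
CC   classes annotated on phenolamine (octopamine/tyramine) receptors.
CC   Patterns follow the public PROSITE release; the file is user-replaceable.
ID   ASN_GLYCOSYLATION; PATTERN.
AC   PS00001;
DE   N-glycosylation site.
PA   N-{P}-[ST]-{P}.
//
ID   CAMP_PHOSPHO_SITE; PATTERN.
AC   PS00004;
DE   cAMP- and cGMP-dependent protein kinase phosphorylation site.
PA   [RK](2)-x-[ST].
//
ID   PKC_PHOSPHO_SITE; PATTERN.
AC   PS00005;
DE   Protein kinase C phosphorylation site.
PA   [ST]-x-[RK].
//
ID   CK2_PHOSPHO_SITE; PATTERN.
AC   PS00006;
DE   Casein kinase II phosphorylation site.
PA   [ST]-x(2)-[DE].
//
ID   MYRISTYL; PATTERN.
AC   PS00008;
DE   N-myristoylation site.
PA   G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}.
//
ID   AMIDATION; PATTERN.
AC   PS00009;
DE   Amidation site.
PA   x-G-[RK]-[RK].
//
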