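taxon	species	category	protein_id	status	flags
Myxosporea	Myxobolus pronini	cytochrome_c	MpCytC	intact
Myxosporea	Thelohanellus kitauei	cytochrome_c	TkCytC	intact
Myxosporea	Myxobolus honghuensis	cytochrome_c	MhCytC	intact
Myxosporea	Enteromyxum leei	cytochrome_c	ElCytC	pseudogene
Myxosporea	Sphaeromyxa zaharoni	cytochrome_c	SzCytC	pseudogene
Myxosporea	Kudoa iwatai	cytochrome_c	KiCytC	pseudogene
Myxosporea	Henneguya salminicola	cytochrome_c	HsalCytC	absent_marker
Myxosporea	Myxobolus squamalis	cytochrome_c	MsquCytC	absent_marker
Malacosporea	Buddenbrockia plumatellae	caspase	BuddCasp	intact
Malacosporea	Buddenbrockia plumatellae	cytochrome_c	BuddCytC	intact
Malacosporea	Tetracapsuloides bryosalmonae	cytochrome_c	TetrCytC	intact
Polypodium	Polypodium hydriforme	caspase	PolCasp	intact
Polypodium	Polypodium hydriforme	caspase	PolCARDCasp	intact	initiator_card
Polypodium	Polypodium hydriforme	bcl2_multidomain	PolBCL-2-1	intact
Polypodium	Polypodium hydriforme	bcl2_multidomain	PolBCL-2-2	intact
Polypodium	Polypodium hydriforme	bcl2_multidomain	PolBOK	intact
Polypodium	Polypodium hydriforme	bcl2_multidomain	PolBAK-1	intact
Polypodium	Polypodium hydriforme	bcl2_multidomain	PolBAK-2	intact
Polypodium	Polypodium hydriforme	iap	PolIAP	intact
Polypodium	Polypodium hydriforme	apaf1	PolAPAF-1	intact
Polypodium	Polypodium hydriforme	p53	PolP53	intact
Polypodium	Polypodium hydriforme	cytochrome_c	PolCytC	intact
Polypodium	Polypodium hydriforme	calpain	PolCalp-5	intact
Polypodium	Polypodium hydriforme	calpain	PolCalp-7	intact
Polypodium	Polypodium hydriforme	calpain	PolClassCalp-1	intact	classical
Polypodium	Polypodium hydriforme	calpain	PolClassCalp-2	intact	classical
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspA	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspB	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspC	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspD	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspE	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspF	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspG	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspH	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspI	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspL	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCaspM	intact
Free-living Cnidaria	Hydra vulgaris	caspase	HyCARDCasp-1	intact	initiator_card
Free-living Cnidaria	Hydra vulgaris	caspase	HyCARDCasp-2	intact	initiator_card
Free-living Cnidaria	Hydra vulgaris	caspase	HyDEDCasp	intact	initiator_ded
Free-living Cnidaria	Hydra vulgaris	caspase	HyDDCasp	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-1	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-2	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-3	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-4	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-5	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-6	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBcl-2-like-7	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBak-like-1	intact
Free-living Cnidaria	Hydra vulgaris	bcl2_multidomain	HyBak-like-2	intact
Free-living Cnidaria	Hydra vulgaris	bh3_only	HyBH3-only-1	intact
Free-living Cnidaria	Hydra vulgaris	bh3_only	HyBH3-only-2	intact
Free-living Cnidaria	Hydra vulgaris	bh3_only	HyBH3-only-3	intact
Free-living Cnidaria	Hydra vulgaris	bh3_only	HyBH3-only-4	intact
Free-living Cnidaria	Hydra vulgaris	death_receptor	HyTNFR-like	intact
Free-living Cnidaria	Hydra vulgaris	adaptor_protein	HyFADD	intact
Free-living Cnidaria	Hydra vulgaris	iap	HyIAP	intact
Free-living Cnidaria	Hydra vulgaris	apaf1	HyAPAF-1	intact
Free-living Cnidaria	Hydra vulgaris	p53	HyP53	intact
Free-living Cnidaria	Hydra vulgaris	cytochrome_c	HyCytC	intact
Free-living Cnidaria	Hydra vulgaris	calpain	HyCalpain-5	intact
Free-living Cnidaria	Hydra vulgaris	calpain	HyCalpain-7	intact
Free-living Cnidaria	Hydra vulgaris	calpain	HyCalpain-9	intact
Caenorhabditis elegans	Caenorhabditis elegans	caspase	Ced-3	intact
Caenorhabditis elegans	Caenorhabditis elegans	caspase	Csp-1	intact
Caenorhabditis elegans	Caenorhabditis elegans	caspase	Csp-2	intact
Caenorhabditis elegans	Caenorhabditis elegans	bcl2_multidomain	Ced-9	intact
Caenorhabditis elegans	Caenorhabditis elegans	bh3_only	Egl-1	intact
Caenorhabditis elegans	Caenorhabditis elegans	bh3_only	Ced-13	intact
Caenorhabditis elegans	Caenorhabditis elegans	apaf1	Ced-4	intact
Caenorhabditis elegans	Caenorhabditis elegans	p53	Cep-1	intact
Caenorhabditis elegans	Caenorhabditis elegans	cytochrome_c	CPS-6	intact
Caenorhabditis elegans	Caenorhabditis elegans	cytochrome_c	WAH-1	intact
Caenorhabditis elegans	Caenorhabditis elegans	calpain	CLP-1	intact
Caenorhabditis elegans	Caenorhabditis elegans	calpain	TRA-3	intact
Homo sapiens	Homo sapiens	caspase	Caspase-1	intact
Homo sapiens	Homo sapiens	caspase	Caspase-2	intact
Homo sapiens	Homo sapiens	caspase	Caspase-3	intact
Homo sapiens	Homo sapiens	caspase	Caspase-4	intact
Homo sapiens	Homo sapiens	caspase	Caspase-5	intact
Homo sapiens	Homo sapiens	caspase	Caspase-6	intact
Homo sapiens	Homo sapiens	caspase	Caspase-7	intact
Homo sapiens	Homo sapiens	caspase	Caspase-8	intact
Homo sapiens	Homo sapiens	caspase	Caspase-9	intact
Homo sapiens	Homo sapiens	caspase	Caspase-10	intact
Homo sapiens	Homo sapiens	caspase	Caspase-12	intact
Homo sapiens	Homo sapiens	caspase	Caspase-13	intact
Homo sapiens	Homo sapiens	caspase	Caspase-14	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bcl-2	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bcl-xL	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bcl-W	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Mcl-1	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bcl-B	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bcl-2A1	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bax	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bak	intact
Homo sapiens	Homo sapiens	bcl2_multidomain	Bok	intact
Homo sapiens	Homo sapiens	bh3_only	Bid	intact
Homo sapiens	Homo sapiens	bh3_only	Bmf	intact
Homo sapiens	Homo sapiens	bh3_only	NOXA	intact
Homo sapiens	Homo sapiens	bh3_only	PUMA	intact
Homo sapiens	Homo sapiens	bh3_only	Bad	intact
Homo sapiens	Homo sapiens	bh3_only	Bim	intact
Homo sapiens	Homo sapiens	bh3_only	Bik	intact
Homo sapiens	Homo sapiens	bh3_only	Hrk	intact
Homo sapiens	Homo sapiens	death_receptor	TNF-R	intact
Homo sapiens	Homo sapiens	adaptor_protein	FADD	intact
Homo sapiens	Homo sapiens	adaptor_protein	TRADD	intact
Homo sapiens	Homo sapiens	iap	XIAP	intact
Homo sapiens	Homo sapiens	iap	NAIP	intact
Homo sapiens	Homo sapiens	iap	c-IAP1	intact
Homo sapiens	Homo sapiens	iap	c-IAP2	intact
Homo sapiens	Homo sapiens	apaf1	APAF-1	intact
Homo sapiens	Homo sapiens	p53	p53	intact
Homo sapiens	Homo sapiens	cytochrome_c	CytC	intact
Homo sapiens	Homo sapiens	calpain	Calpain-5	intact
Homo sapiens	Homo sapiens	calpain	Calpain-7	intact
Homo sapiens	Homo sapiens	calpain	Calpain-9	intact
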