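# Synthetic stand-in transcript models for the nine QPCR-validated internal
# cassette exons. The true exon lengths and sequences live in supplementary
# material not shipped here; these geometries are constructed so that each
# transcript reproduces the documented structural outcome of skipping its
# cassette exon (see ?classify_skip). Coordinates are transcript-relative,
# 1-based inclusive.
transcript_id	exon_index	exon_length	is_cassette	cds_start	cds_end
Pcsk4	1	150	FALSE	30	329
Pcsk4	2	100	TRUE	30	329
Pcsk4	3	120	FALSE	30	329
Pcsk4	4	200	FALSE	30	329
Pcsk4	5	100	FALSE	30	329
Npas2	1	150	FALSE	30	530
Npas2	2	100	TRUE	30	530
Npas2	3	130	FALSE	30	530
Npas2	4	140	FALSE	30	530
Npas2	5	200	FALSE	30	530
Usp2	1	100	FALSE	120	320
Usp2	2	80	TRUE	120	320
Usp2	3	150	FALSE	120	320
Usp2	4	120	FALSE	120	320
Fbxo21	1	120	FALSE	40	489
Fbxo21	2	95	TRUE	40	489
Fbxo21	3	110	FALSE	40	489
Fbxo21	4	160	FALSE	40	489
Fbxo21	5	180	FALSE	40	489
Nr1d1	1	100	FALSE	20	367
Nr1d1	2	99	TRUE	20	367
Nr1d1	3	120	FALSE	20	367
Nr1d1	4	150	FALSE	20	367
Ash2l	1	130	FALSE	25	444
Ash2l	2	120	TRUE	25	444
Ash2l	3	140	FALSE	25	444
Ash2l	4	160	FALSE	25	444
Loxl4	1	200	FALSE	50	499
Loxl4	2	150	FALSE	50	499
Loxl4	3	100	TRUE	50	499
Loxl4	4	250	FALSE	50	499
Adrbk2	1	110	FALSE	15	419
Adrbk2	2	150	TRUE	15	419
Adrbk2	3	125	FALSE	15	419
Adrbk2	4	140	FALSE	15	419
Clock	1	180	FALSE	10	444
Clock	2	120	FALSE	10	444
Clock	3	85	TRUE	10	444
Clock	4	300	FALSE	10	444
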