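set	n_total	n_novel	n_in_ogs	n_ogs	n_ogs_shared_Ngr	n_ogs_shared_Disc	n_ogs_unique
aggup	448	100	190	162	35	75	52
aggdn	453	193	198	176	18	35	123
germup	1649	461	880	558	104	162	292
germdn	2012	371	948	657	133	232	292
proteome	15868	4987	6817	2728	360	605	1763
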