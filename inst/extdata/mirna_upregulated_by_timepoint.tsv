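timepoint	min_log2	column	row	mirna
isc2h_rep0h	1	1	1	miR-215
rep4h	1	2	1	miR-493
rep1d	3	3	1	miR-466d-5p
rep1d	3	3	2	miR-466k
rep1d	3	3	3	miR-466b-5p
rep1d	3	3	4	miR-468
rep1d	3	3	5	miR-466f-5p
rep1d	3	3	6	miR-672
rep1d	3	3	7	miR-669b
rep1d	3	3	8	miR-669e
rep1d	3	3	9	miR-466a-5p
rep1d	3	3	10	miR-466h
rep1d	3	3	11	miR-210
rep1d	3	3	12	miR-670
rep1d	3	3	13	miR-467c
rep1d	3	3	14	miR-466e-5p
rep1d	3	3	15	miR-669a
rep1d	2	4	1	miR-467e
rep1d	2	4	2	miR-466c-5p
rep1d	2	4	3	miR-466j
rep1d	2	4	4	miR-669d
rep1d	2	4	5	miR-125b-3p
rep1d	2	4	6	miR-16
rep1d	2	4	7	miR-669g
rep1d	2	4	8	miR-696
rep1d	2	4	9	miR-18b
rep1d	2	4	10	miR-297a
rep1d	2	4	11	miR-297c
rep1d	2	4	12	miR-493
rep1d	2	4	13	miR-467h
rep1d	2	4	14	miR-297b-5p
rep1d	2	4	15	miR-15a
rep1d	2	4	16	miR-669c
rep1d	2	4	17	miR-467b
rep1d	2	4	18	miR-1188
rep1d	2	4	19	miR-122
rep1d	2	4	20	miR-711
rep1d	2	4	21	miR-466f
rep1d	2	4	22	miR-214
rep1d	2	4	23	miR-99b
rep1d	2	4	24	miR-465b-5p
rep1d	2	4	25	miR-346
rep1d	2	4	26	miR-673-3p
rep1d	2	4	27	miR-681
rep1d	2	4	28	miR-93
rep1d	2	4	29	miR-1906
rep1d	2	4	30	miR-1186
rep1d	2	4	31	miR-546
rep1d	2	4	32	miR-342-5p
rep1d	2	4	33	miR-21
rep1d	1	5	1	miR-1903
rep1d	1	5	2	miR-296-3p
rep1d	1	5	3	miR-677
rep1d	1	5	4	miR-744
rep1d	1	5	5	miR-669h-5p
rep1d	1	5	6	miR-106b
rep1d	1	5	7	miR-683
rep1d	1	5	8	miR-1196
rep1d	1	5	9	miR-449b
rep1d	1	5	10	miR-1194
rep1d	1	5	11	miR-338-5p
rep1d	1	5	12	miR-760
rep1d	1	5	13	miR-1892
rep1d	1	5	14	miR-141
rep1d	1	5	15	miR-330
rep1d	1	5	16	miR-689
rep1d	1	5	17	miR-547
rep1d	1	5	18	miR-574-5p
rep1d	1	5	19	miR-1187
rep1d	1	5	20	miR-298
rep1d	1	5	21	miR-98
rep1d	1	5	22	miR-449c
rep1d	1	5	23	miR-680
rep1d	1	5	24	miR-105
rep1d	1	5	25	miR-712
rep1d	1	5	26	miR-291a-5p
rep1d	1	6	1	miR-542-5p
rep1d	1	6	2	miR-92a
rep1d	1	6	3	miR-292-5p
rep1d	1	6	4	miR-764-3p
rep1d	1	6	5	miR-30b
rep1d	1	6	6	miR-705
rep1d	1	6	7	miR-20b
rep1d	1	6	8	miR-294
rep1d	1	6	9	miR-764-5p
rep1d	1	6	10	miR-1907
rep1d	1	6	11	miR-881
rep1d	1	6	12	miR-1896
rep1d	1	6	13	miR-423-5p
rep1d	1	6	14	miR-691
rep1d	1	6	15	miR-7a
rep1d	1	6	16	miR-292-3p
rep1d	1	6	17	miR-302c
rep1d	1	6	18	miR-1893
rep1d	1	6	19	miR-1224
rep1d	1	6	20	miR-302d
rep1d	1	6	21	miR-214
rep1d	1	6	22	miR-28
rep1d	1	6	23	miR-710
rep1d	1	6	24	miR-291b-5p
rep1d	1	6	25	miR-685
rep1d	1	6	26	miR-877
rep1d	1	7	1	miR-370
rep1d	1	7	2	miR-135a
rep1d	1	7	3	miR-218
rep1d	1	7	4	miR-770-3p
rep1d	1	7	5	miR-383
rep1d	1	7	6	miR-674
rep1d	1	7	7	miR-31
rep1d	1	7	8	miR-190b
rep1d	1	7	9	miR-433
rep1d	1	7	10	miR-671-3p
rep1d	1	7	11	miR-682
rep1d	1	7	12	miR-450b-5p
rep1d	1	7	13	miR-743b-5p
rep1d	1	7	14	miR-665
rep1d	1	7	15	miR-667
rep1d	1	7	16	miR-1898
rep1d	1	7	17	miR-488
rep1d	1	7	18	miR-511
rep1d	1	7	19	miR-679
rep1d	1	7	20	miR-453
rep1d	1	7	21	miR-678
rep1d	1	7	22	miR-615-5p
rep1d	1	7	23	miR-1897-5p
rep1d	1	7	24	miR-101a
rep1d	1	7	25	miR-693-3p
rep1d	1	7	26	miR-327
rep1d	1	7	27	miR-129-5p
rep7d	2	8	1	miR-21
rep7d	2	8	2	miR-466d-3p
rep7d	2	8	3	miR-467b
rep7d	2	8	4	miR-551b
rep7d	2	8	5	miR-467e
rep7d	2	8	6	miR-466g
rep7d	2	8	7	miR-297a
rep7d	2	8	8	miR-467g
rep7d	2	8	9	miR-467a
rep7d	1	9	1	miR-214
rep7d	1	9	2	miR-466l
rep7d	1	9	3	miR-466f-3p
rep7d	1	9	4	miR-669i
rep7d	1	9	5	miR-466i
rep7d	1	9	6	miR-466a-3p
rep7d	1	9	7	miR-31
rep7d	1	9	8	miR-669f
rep7d	1	9	9	miR-574-3p
rep7d	1	9	10	miR-669h-3p
rep7d	1	9	11	miR-467f
rep7d	1	9	12	miR-215
rep7d	1	9	13	miR-466b-3-3p
rep7d	1	9	14	miR-142-3p
rep7d	1	9	15	miR-207
rep7d	1	9	16	miR-1192
rep7d	1	9	17	miR-713
rep7d	1	9	18	miR-674
rep7d	1	9	19	miR-199a-5p
rep7d	1	9	20	miR-206
rep7d	1	9	21	miR-706
rep7d	1	9	22	miR-1-2-as
rep7d	1	9	23	miR-1903
rep7d	1	9	24	miR-197
rep7d	1	9	25	miR-15b
rep7d	1	10	1	miR-501-3p
rep7d	1	10	2	miR-199a-3p
rep7d	1	10	3	miR-464
rep7d	1	10	4	miR-698
rep7d	1	10	5	miR-582-3p
rep7d	1	10	6	miR-488
rep7d	1	10	7	miR-1186
rep7d	1	10	8	miR-330
rep7d	1	10	9	miR-335-3p
rep7d	1	10	10	miR-222
rep7d	1	10	11	miR-351
rep7d	1	10	12	miR-346
rep7d	1	10	13	miR-467h
rep7d	1	10	14	miR-878-3p
rep7d	1	10	15	miR-717
rep7d	1	10	16	miR-1196
rep7d	1	10	17	miR-685
rep7d	1	10	18	miR-671-3p
rep7d	1	10	19	miR-542-3p
rep7d	1	10	20	miR-669d
rep7d	1	10	21	miR-467b
rep7d	1	10	22	miR-503
rep7d	1	10	23	miR-1894-5p
rep7d	1	10	24	miR-877
rep7d	1	10	25	miR-667
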