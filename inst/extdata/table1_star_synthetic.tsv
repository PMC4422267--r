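# SYNTHETIC star-evidence flags for the packaged novel-miRNA table. The source
# table records only that a miRNA* read was observed in at least one library for
# the seven star-evidenced candidates (miRn7-miRn13), not in which library; here
# the flag is placed in the library of maximum mature TPM. 1 = star detected.
candidate_id	S10	S15	S21	S27	S35	I10	I15	I21	I27	I35
miRn1	0	0	0	0	0	0	0	0	0	0
miRn2	0	0	0	0	0	0	0	0	0	0
miRn3	0	0	0	0	0	0	0	0	0	0
miRn4	0	0	0	0	0	0	0	0	0	0
miRn5	0	0	0	0	0	0	0	0	0	0
miRn6	0	0	0	0	0	0	0	0	0	0
miRn7	0	0	0	0	0	0	0	0	0	1
miRn8	0	0	0	0	0	1	0	0	0	0
miRn9	0	0	0	0	0	1	0	0	0	0
miRn10	0	0	0	0	0	1	0	0	0	0
miRn11	0	0	0	0	0	0	0	1	0	0
miRn12	0	0	0	0	0	0	0	1	0	0
miRn13	0	0	0	0	0	1	0	0	0	0
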