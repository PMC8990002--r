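accession	composition	topology
SYN0001	Hex(3)HexNAc(2)	pep(HexNAc(HexNAc(Hex(Hex)(Hex))))
SYN0002	Hex(4)HexNAc(2)	
SYN0003	Hex(5)HexNAc(2)	
SYN0004	Hex(6)HexNAc(2)	
SYN0005	Hex(7)HexNAc(2)	
SYN0006	Hex(8)HexNAc(2)	
SYN0007	Hex(9)HexNAc(2)	
SYN0008	Hex(3)HexNAc(2)Fuc(1)	
SYN0009	Hex(2)HexNAc(2)	
SYN0010	Hex(1)HexNAc(2)	
SYN0011	Hex(2)HexNAc(2)Fuc(1)	
SYN0012	Hex(3)HexNAc(3)	
SYN0013	Hex(3)HexNAc(4)	
SYN0014	Hex(3)HexNAc(5)	
SYN0015	Hex(4)HexNAc(3)	
SYN0016	Hex(5)HexNAc(3)	
SYN0017	Hex(6)HexNAc(3)	
SYN0018	Hex(4)HexNAc(4)	
SYN0019	Hex(4)HexNAc(5)	
SYN0020	Hex(5)HexNAc(4)	
SYN0021	Hex(5)HexNAc(4)Fuc(1)	
SYN0022	Hex(5)HexNAc(4)NeuAc(1)	
SYN0023	Hex(5)HexNAc(4)NeuAc(2)	
SYN0024	Hex(5)HexNAc(4)NeuAc(1)Fuc(1)	
SYN0025	Hex(5)HexNAc(4)NeuAc(2)Fuc(1)	
SYN0026	Hex(6)HexNAc(5)	
SYN0027	Hex(6)HexNAc(5)NeuAc(1)	
SYN0028	Hex(6)HexNAc(5)NeuAc(2)	
SYN0029	Hex(6)HexNAc(5)NeuAc(3)	
SYN0030	Hex(6)HexNAc(5)Fuc(1)NeuAc(1)	
SYN0031	Hex(7)HexNAc(6)	
SYN0032	Hex(7)HexNAc(6)NeuAc(1)	
SYN0033	Hex(5)HexNAc(5)	
SYN0034	Hex(5)HexNAc(5)NeuAc(1)	
SYN0035	Hex(4)HexNAc(3)NeuAc(1)	
SYN0036	Hex(4)HexNAc(3)NeuAc(1)Fuc(1)	
SYN0037	Hex(4)HexNAc(4)Fuc(1)	
SYN0038	Hex(3)HexNAc(4)Fuc(1)	
SYN0039	Hex(3)HexNAc(5)Fuc(1)	
SYN0040	Hex(5)HexNAc(4)NeuGc(1)	
SYN0041	Hex(5)HexNAc(4)NeuGc(2)	
SYN0042	Hex(4)HexNAc(4)NeuGc(1)	
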