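"sample_id","rna_chain","rna_v","rna_j","rna_proportion_pct","rna_cdr3_aa","rna_productive","dna_v","dna_d","dna_j","dna_proportion_pct","dna_cdr3_aa","dna_productive","dna_failure_reason","cdr3_source"
"PLC-01","IGH","IGHV3-48","IGHJ4",92.9,"CARDSYEDYVYW",TRUE,"IGHV3-30*09",NA,"IGHJ4*02",67.55,"CARDSYEDYVYW",TRUE,"none","printed"
"PLC-02","IGH","IGHV3-21","IGHJ4",97.93,"CARYQLDAVAGKWGHYFDYW",TRUE,"IGHV3-21*01",NA,"IGHJ4*02",74.39,"CARYQLDAVAGKWGHYFDYW",TRUE,"none","printed"
"PLC-03","IGH","IGHV3-43","IGHJ5",97.77,"CAKARLPLVGGLDSW",TRUE,"IGHV3-9*01",NA,"IGHJ4*02",66.23,"CAKARLPLVGGLDSW",TRUE,"none","printed"
"PLC-05","IGH","IGHV3-43","IGHJ6",49.79,"CTRVIGSGASCYDCYYHGMDVW",TRUE,"IGHV3-9*01",NA,"IGHJ6*02",13.62,"CTRVIGSGASCYDCYYHGMDVW",TRUE,"none","printed"
"PLC-06","IGH","IGHV3-53","IGHJ5",87.91,"CARGLTAPGFPLDSW",TRUE,"IGHV3-53*01",NA,"IGHJ4*02",57.58,"CARGLTAPGFPLDSW",TRUE,"none","printed"
"PLC-07","IGH","IGHV3-23","IGHJ6",65.26,"CAKGRADCTDGVCYRRYGMDVW",TRUE,"IGHV3-23*01",NA,"IGHJ6*01",56.92,"CAKGRADCTDGVCYRRYGMDVW",TRUE,"none","printed"
"PLC-08","IGH","IGHV3-43","IGHJ4",99.44,"CVKGQGGYTYGGFDCW",TRUE,"IGHV3-43*01",NA,"IGHJ4*02",81.44,"CVKGQGGYTYGGFDCW",TRUE,"none","printed"
"PLC-10","IGH","IGHV5-51","IGHJ4",77.63,"CARTNWPYYFDHW",TRUE,"IGHV5-51*01",NA,"IGHJ4*02",57.39,"CARTNWPYYFDHW",TRUE,"none","printed"
"PLC-12","IGH","IGHV3-43","IGHJ4",93.73,"CARDRYQLIIYYFDRW",TRUE,"IGHV3-9*01",NA,"IGHJ4*02",62.86,"CARDRYQLIIYYFDRW",TRUE,"none","printed"
"PLC-15","IGH","IGHV3-43","IGHJ4",98.97,"CAKDVRYGYGSTQSAGFDYW",TRUE,"IGHV3-9*01",NA,"IGHJ4*02",32.77,"CAKDVRYGYGSTQSAGFDYW",TRUE,"none","printed"
"PLC-17","IGH","IGHV4-39","IGHJ4",95.53,"CARDKTTMTFSSPIFDYW",TRUE,"IGHV4-39*07",NA,"IGHJ4*02",22.1,"CARDKTTMTFSSPIFDYW",TRUE,"none","printed"
"PLC-18","IGH","IGHV2-5","IGHJ1",95.78,"CAHSGSMWSGYAGTEYFQHW",TRUE,"IGHV2-5*02",NA,"IGHJ1*01",56.58,"CAHSGSMWSGYAGTEYFQHW",TRUE,"none","printed"
"PLC-19","IGH","IGHV4-59","IGHJ4",67.5,"CARAGDYDLLLLDYW",TRUE,"IGHV4-59*01",NA,"IGHJ4*02",21.08,"CARAGDYDLLLLDYW",TRUE,"none","printed"
"PLC-21","IGH","IGHV5-51","IGHJ6",80.02,"CARLPQGGYYYMDVW",TRUE,"IGHV5-51*03",NA,"IGHJ6*03",56.06,"CARLPQGGYYYMDVW",TRUE,"none","printed"
"PLC-22","IGH","IGHV3-53","IGHJ5",85.1,"CARGLTAPGFPLDSW",TRUE,"IGHV3-53*01",NA,"IGHJ4*02",77.01,"CARGLTAPGFPLDSW",TRUE,"none","printed"
"PLC-23","IGH","IGHV3-33","IGHJ1",56.11,"CAFAIGADGEYFQHW",TRUE,"IGHV3-30-3*02",NA,"IGHJ1*01",61.13,"CAFAIGADGEYFQHW",TRUE,"none","printed"
"PLC-24","IGH","IGHV2-70","IGHJ4",69.68,"CARGASETQVAMSTAELYFFDSW",TRUE,"IGHV2-70*01",NA,"IGHJ4*02",40.67,"CARGASETQVAMSTAELYFFDSW",TRUE,"none","printed"
"PLC-14","IGH","IGHV1-18","IGHJ4",98.08,"CARDGYSSGWFDPW",TRUE,"IGHV3-23*01","IGHD3-9*01","IGHJ5*02",78,NA,FALSE,"stop_codon","synthetic"
"PLC-16","IGK","IGKV1-33","IGKJ3",79,"CQQYDNLPLTF",TRUE,"IGHV3-11*05","IGHD3-3*01","IGHJ5*02",29.97,NA,FALSE,"stop_codon","synthetic"
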