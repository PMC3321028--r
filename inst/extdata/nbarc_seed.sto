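# STOCKHOLM 1.0
nbarc_cc1_1  ETLESAIGPLGMGGVGKTTLAQIFAKRTHGKGTAPSAKENDLWSAVDEVDVQYHAWLGAIMMSWQEHKRYLEVLDDVWLMTDVSHLKSIRIRARSAGSRIIVTSRNVAIAAAQVRTLNEQIMSVNVVAIDEQASVTQSLTFPKLQDGLPLALKVGDEIFAQPGLTHASY
nbarc_cc1_2  CTLESAILPLNMGGVGKTTLAQIIAKRTHGRGMAPSAKENDYWSAVDIVDVQIDAWTGAKMMSWQEHKRYLIVLDDVWCMTDVPHLKHIRIRARSAGARIIVTSRNVALAAAQVRTLNEQIMSVNVVAIDEQASNTESLTFPKLQDGLPLALQVGDEHFAQMGATKAKY
nbarc_cc1_3  CTLESAIVPLLMGGVRKTTLAQIFAKRTHGIGTAPSAKENDLWSAVDISDVQYDAWNGAIMMSWQEHKRQLIVLDDVWCMTDVSHLKSIRIRARSAGSRIIVTSRIVALAAAQVRTLNEQIMSVNEVAADEQASVTFSLTFTKLGDGLPLALKVGDEIFAQPGAAKAKY
nbarc_cc1_4  CTLFSAIGPLGMGGVGKTTLAPIFAKRTHGITTRPSAKKNDKWSAVDIVDVQEDAWLGAIMMSWQEHKRYLIVLDDVWCMTDVGHLKSIRIRARSAGSRGIVTSRNVALAAAQVRTLNTQIMSVNVVAIDEQASVTESLTFPKLQDGLPLALKVGDEIFAQPGATKAKY
nbarc_cc2_1  CTLESAIGPLGMGGVGLTTLAQNLGLAVPKSGKFDNPFIYWDQGQRSIVDVQYHATLGAIMMSWVEHKRYLIVLDDVWCMTDVSHLKSIRIRARSAGSRIIVTSRNVALAAAQVRTLNIQIMSVNVISLGRATADTALKVKFSGCKHLPLALKVGDEIFAQPGATKLKY
nbarc_cc2_2  CTLESAIGPLGMPGVGKTTLAQNLGLAVPKSGKFDNPFIDWDQGQRMIVDVQYDAWLGAIMMSWQEHKRYLIVLDDVWCWTDVSHLKSIRIRARSAGSRIIVTSRNVALGAAQMRTLNEQIMSVNVISLGRATAPTALGVKFSGCKGLPLALKVGDENFAQPGATKAKY
nbarc_cc2_3  CTLESAIGPHGMGGVGKTVLAQNLGLAVPKSGVFDNPFIYWDQGQRSIVDVQYDAWLGAIMMSWQEHKRYLIVLDDVWCMTDVSHLKSIRIRARSADSRIIVTSRNVALAAAQVRDLNEQGMSINVISLGRATADTALGVKFSGCKGLPLALKVGDEIFADGAATKAKY
nbarc_cc2_4  CTLYSAIGPLGMGGVGKTTLAQNLVLAVPKSGKFDNPFIYWDQGQASIVSVQYSAWLGAIMMSWQEHKRYLIVLDDVWCMTDVSHAKSIRIRLRSAGSRIIPTSTNVALAAAQVRTLNEQIMSFNVISISRATADTALGQKFSGCKWLFLPLKVGDEKFAQPGATKAKY
nbarc_tir_1  CTLESAIGPGIMMGVGKTTLAQDDGLHKKDWRALMSTLLGLESPSLLIVDVQYDAWYGAIMMSWQEHKRYLIVVDDVDCMTDVSHLKSIRIRARSLGSRIIVTSRNVALAAAQVRTLNEQIMSVNVDNGSDLTMLCNQTACLTKRPGLPLALTVGDEMFAQPGATKAKY
nbarc_tir_2  CTLESAIGPLGMGGVGKTTLAQMDGLHKKDWRALKCTARGLESSSLLQVDVQYDAWLGAIMMSWQEHKRYLIVLDDVDCMTDVSHLRSARIRARSAGSRIIDTSRNVALAAAQVRTLNEQIPSVNVAVGSDQTMWCEQTACLTKRPGLPLALKVGDEIFAQPGATKAKY
nbarc_tir_3  CTLESAYGPLGMGGVGKTTVAQMDGLHKVDWRNDMSTLLGLEFSMLLKVAVQYDAWLGAIMMSWQEHKRYLIVDDDVDCMTDVSHLKSTRIRARSAGDRPIYTSRNVALAAAQVRTLNEQIMSVNVDNGSDQTMLCNQTRCLTKRPGLPLALLVGDEIFCPPGATKAKY
nbarc_tir_4  CTLESAIGPLIMGGVGKTTLAQMDGLHKKDWRALMSTLLGLESSSLLIVDVQYDAWLGAIMMSWQEHKRYLIVLDDVDCMTDVSHLKSINIRARSGGSRIIVTSRNVALDGAQVRTLNEQIMSANVDNGSDQTMLCNQTAALTKRPGLPLALKVGDEIFAQPSATKDKY
//
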