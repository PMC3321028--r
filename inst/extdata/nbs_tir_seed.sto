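# STOCKHOLM 1.0
nbs_tir_1  CTLESAIAPLGMLGVGKTTNAQMDGLGKKDWRALMSTLLGLESSSLLIVDVQYDAWLGAPMMSWQEHTRYLIVLDDVDCMTWVSHLKSIRIRARSAGSRIILTSRNVALAAAQVRQLNEQIMSVNVDNGSDQTMLCNQTACLTKRPGLQLTLKVGDESFAQPVATKAKY
nbs_tir_2  CTLESAIGPLGMGGVGKSTLANMDVLHKKDWEAPMSTLLGLECSSLLIVDVQYDAWLGWIMMSWQRHKRYNIVLDVVDCMTDVSHLKSIRPRARSAGSRIIVTSRNTALAAAQVRTLNEQIASVNVDDGFDQTMLCNQTACLTKRPGLPLALKVGDLIFAQCGETKAKE
nbs_tir_3  CTLESAIGPLGMRGVGKHTLAQMDGPHKKDWRALMSTLLGLESSSLLIVVVQYDANLGAIMMSWQCHKRYLIVLDDNDCMTDVAHLKSVRIRARSEGSRIIVTSRNVALAAAQVRTLNEQIMSVNVDNGSDCTMLCNQTPFLTKRPGLPLALKVGDEIFAQPDTTKAKA
nbs_tir_4  CTTESAIGPLDMGGNVKTTLAQMDGLHKKDARALMSTLLGLESSSLLIVGVQYQAWLGAIMMSWQEHKRYKIVLDDVDCMTDVSHLGSIRIRARSAGSRILVTSRNVALAAAQVRTLNEAIMSVNVDNGSDQTMLCNQTACLTKRPGLPLALKVGIEIFAQLGAAKAKY
nbs_tir_5  CTLESAIGPLGMGGVGKTTLAQMDGLHKKDWRAGMSTLLGLESSSLLIVDVQYDAWLAAIMMSWQEHKRYLIVLDDVDCMTDVSHSKSIRIRARSAGSRIIVTSRNVALAAAQVRSLNEQIMSVNVDNGSDQTMLCNQTACLTKRPGLRLALKVGDEIFAQPGATKAKY
nbs_tir_6  CTLESAIGPLGMGGVGKITLFQMDGLHKKDWRALMSTLLGLESSSLLIVDVQYDAWLGAIMMGWQEHKRYLIVAGDVDCMTDVSHLKSIRIRARSAGSRIIVTSRNVALAAAQVRTLNEQIMSVNVDNGSDQTMSCNQTACLTKRPGLPLALKVGDEIFAQPGATKAKY
nbs_tir_7  CILESRIGPLGMGGVGKLTLAQMVGLHKKDWRALMSTLLGLESSSLLIVDVQYDGWLGTIMMSWQEHERYLIDLDDVDCMTDVHHLKSIRIWARVAGSSIIVRIRTDALAAADVRTANEQIMSVAVDNGSDQTMLCNQRACLTKQDGLVLALKVGDEVFAQPGATKAKY
nbs_tir_8  CYLTPAKGPLVMGGVGKTTLAQMDGLHKKDLRALMSTLVGLPSSSLLIVDVQYDAPLGAIYMKWQEHKRYLIVLDDVDCMTDVSHLKSIRIRARSAGSRIIVTSRNVALAAAQVRTLNEQIMSVNVDNGSDQTMLCNQTACLTKRPGLPLALKVGDEIFAQPGATLAKY
//
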