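# STOCKHOLM 1.0
nbs_cc1_1  CTLESAIGYLGLAGVGKTTLAQIFAKRTHGIGTAPSATEVDLWSAVDIVDVQYDAWLGAIMMSWQEHKRYLIVLDYVWCMTDVSHLKSIRIRARSAGSRIIVTSRNVALAAAQVRTLSEQIMSVNVVALDEQASTTESHTFPKLWDGLKLALKVGDEKIAQPGDTKAKY
nbs_cc1_2  CTLESAIGPLGMGGVGKRTLAQIFEKRTHGIGTAPSAKENDLWSAVDIVDVQYDAWLGAYMMSWQEHKRYLIVLDDVWCMTDVSKLKSIRIRARSQGSRIIVTSRNVAELAAQVRTLNEQIMSVNVVAIDEQASVTESLTFPKLQDGLPLAVKVGDEIFAQPGATKALY
nbs_cc1_3  CTLESAIGPLGMGGNGKTTVAQIFAQREHGINTAPSAPENDLWSAVDQFDVQYDAWLGAIMMSWQEHKRSLIVLDDVGCMTDVSQLKSIRGRARSAGSRIIVTSRNVDLAAAQVRTLNEEIMRVNVVAIDHQCSVTESLTFPDLQDGLPLALKLGDEIFAQPGATKAKL
nbs_cc1_4  CTLESAIGPLGMGGVGKTTLAQIFAKRTHGIGTAPSAKEDDLWSKVDRVDVQYDAHLGAIMMSWQEHKRYLIVLDDVWCMTDVSHLSSIRIEARSAGSRIIVTSQNVALAAADVRTLNEDIMSVNVVAIDEQASVTESLTEPKLQDGLILALKVGDEIPYQPPATKAKY
nbs_cc2_1  CTLEEAILPLGMGGVGKTTLAQNLGLAVPKSGKFDNPFIYWDQGQRSIVDVQYIAWLGAIMMSTQEHKRYLIVLDDVWCMTDVSHLKSIHIRARSAGSRINVTSRNVALAAAVVRTLNEQIGSVNVISTGRMTADTALGVKFSGCNGLPLALKVGDEIFAHPGATKAKY
nbs_cc2_2  CTLESAIKPLGMGGVGKTTLAQNLTLAVPKSGKFDNPFIYWDQGVRSIVDVQYGAWLVAIMMSWQEAKRYLIVLDDVWCMTDVSHLKSIRIRARSAGSRIIVTSPNVALAAEQVRTNNEQIMSVNVISLGRATADTALGVKLIGCKGLPLALKVGDEIFAQPGATKAAY
nbs_cc2_3  STLESAIGPLLMGGVGKLTLAQNLGLVVPKSGKFDNPFIYWDQGIRSIVDVQYDAWLGAIIVSWTEHKRYLIVLDDVWCMTDLSHLKSIRIRAPSAGSGIIVPSRNVALAAAQVRTRNEQIMSVNVISLGRATADTALGVKFSGCKGAPLALKVGDEIFAGPGATKAKY
nbs_cc2_4  CTLESAIGPLGMGGVGKTTLAQNLGLAVPKSGKFGNPKIYWDQSQRSIVDVQYDAWLGAIMMSWQEHKRYLIVLDDVWCMTDVSHLKQISIRARSAGSRIIVTSRNQALAAAQVRTLNEQISSVNVISLGRATAVTALHVKFSGCKGLPLALKVGDEIFAQPGATKAKY
//
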