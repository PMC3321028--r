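# STOCKHOLM 1.0
kinase_1  GMGGVGKTTLKQVPRVPFMHKTVESLLVLSTYSSGSFVKVYKQRSKTPNAAFAYLAHEIQHRDLKPENLLFEKQDHSLLLLHNAHPLGFCNPEAQDFGLAAETDKVRFPNFLFSFPIMSLGGGTPEYMAPEVKQGITRFKVSHLTADLESLGGIWSP
kinase_2  GMGGVGKTTVAAVPRVPFMHNTVESLLVLSTYGSGSFGKVYKQRSETPNAAGAYLAHEIQHRDNKPINLLFEKQDHSLTLGHNLHPLGFCNPEAQDFGLARETDKVRFPDFLFSFDIMSLLDGTSEYMAPEVRSGITRFKVSHLTADLLSLLGIELP
kinase_3  GMAGVGKTTPAQVPRVFFMHKTVESLLVLSTYGSASFGKVYKFRSETPPAAEAYLAHEIQHRDLKPENLLFEKQDHSLTLGHNLHPLGFCNPEAQDFGLARFTDKVRFPDFLFSFPIMSLGDGTPEYMAPEVKSGITRFKVSHLTADLESLLGIWSP
kinase_4  GMGGVGKTTLAQVPSVPPMHKTVESLLVLSTYGSGSFGKVYKQRSETPNLAQSYLAHEIQHKDLKPENLLKEKQDHSLTLGHNLHLLGFCNPEAQDFGLARETRKVRFPDFAFSFDIMSYGDGTPEYMAPEVKSGITRFKVSHLTADLFSLLGIKSP
kinase_5  GMGCVGKTTLAQVPRVPFMHKTVESLLVASTGASGSFGKCYKQRSETPNAATLYLAHEIQHRDLKPENLLFEKQDHSSTLGHNLHPLGFCNPMAQDFGLAREPDKVRFPDFLFSFDIMSLGDGTPEYMAPEVKTGIGRFKVSHLFADLECILGIWSP
kinase_6  GMGNVGKTILAQVERVNFMHKTVESLLVLSTYGSGSFGKVYKQRSETPFAAEAYVAKEIQARDLKPEILLFEKQDHSLTLGHNLHPLDICNEEAQDFGLAKETDKVRFPDFLFSFDIMSLGDGTPEYMAPEVKSGITRFKVSHLTELLESLLGIWSP
kinase_7  GQGGVGKTTLAQVPRVPFMHKTVESLLVLSTYGSGSFIKVYKQRSETPNAAEAYLAHEIDHRDLKPENLLFEKQDHGLTLLHNLHPLGFCNPSALDFGCARETDKVRFKDFLFSFDIMSLGDGTPEYMAPEVKSGIDRFKVSHLTADLESLLGIWSP
kinase_8  GMGGVGKTTLAQVPRVPFMHKTGESLPVLSTYGSGSFGKMYKQRLETPNAAEAYLAHEIQHRDLKPENLLFEKQDHSLTLGHNLHPLGFCNPEAQDFGLARETDKVRFPDFLFSFDIMSLGDGTPEGMAPEVKSGITRFKVSHLTADLESLLDIWSP
//
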