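>Abeta42
DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA
>SAA1
RSFFSFLGEAFDGARDMWRAYSDMREANYIGSDKYFHARGNYDAAKRGPGGVWAAEAISD
ARENIQRFFGHGAEDSLADQAANEWGRSGKDPNHFRPAGLPEKY
>tau
PGGGKVQIINKKLDLSNVQSKCGSKDNIKHVPGGGSVQIVYKPVDLSKVTSKCGSLGNIH
HKPGGGQVEVKSEKLDFKDRVQSKIGSLDNITHVPGGGNKKIETHKLTFRENAKAKTDHG
AEIVYK
>TTR
GPTGTGESKCPLMVKVLDAVRGSPAINVAVHVFRKAADDTWEPFASGKTSESGELHGLTT
EEEFVEGIYKVEIDTKSYWKALGISPFHEHAEVVFTANDSGPRRYTIAALLSPYSYSTTA
VVTNPKE
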