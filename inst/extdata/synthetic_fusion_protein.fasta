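>synthetic_fusion synthetic 438 aa fusion protein
CNAKDFPGIHFSEPPGSVSTRMPAGRVAADGRGMEHETSGAVHRHLGCPTCAGRCWTLAS
GTPLINVHPIAKSSATPGTAARQDIARVRPVHALILPLRGVEVPLAQRAPQSYRVGLGLA
LSLDSKGFRMLLPGVSSAPSRPAEQREGKLIPTRSGAFVYKPETVESGYGLYWSYYCVRT
VHCPSSIQDNVKGAGLLIRDNQQDRLEEVQVRIARYRLPSMSACLAALALSILASIMNKK
WRAQHTGRGLSTDYGLPKSHGVGCPSSPAYILLNTIDRASATWTSDYGDCRRGMCATNEF
EIGCTRLVARARSHLGLAKRILSLIGSDRYELNSSPRPAGMIVQVHELTSWGATRGYRHD
ALRNSFKVAGMRCTRIAGGQKRVEQRPNIYRCAAFSIDLVESTLAYEPEERICYALRRVA
DNWRAQPRVVLRRPLAKS
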