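>collagen_alpha1_synthetic
QADFHDSVLVHGVDHGPAGAPGKQGSPGPPGSFGPAGRLGPSGSDGELGPPGEMGAPGKD
GATGSAGDPGALGAMGEPGKDGLFGPPGLPGEFGPEGLVGAPGPSGAAGPVGEPGRAGAA
GSPGENGAPGSDGESGKMGRNGAQGAAGPPGDDGEPGAPGESGPAGSPGRPGPPGPVGKD
GPTGPMGPLGSAGPAGEVGEVGPAGPQGPSGLLGPDGLMGEVGETGAAGPTGSFGAEGPP
GPMGRTGPPGAEGLQGPAGPPGSPGELGSPGAFGENGAEGDLGKTGPPGPPGDEGSLGRD
GRPGAMGEPGPNGKEGLPGSPGKTGRPGKFGPPGPPGSTGPLGPNGLNGDEGLPGLPGET
GAMGSPGSPGPPGREGLNGPPGPNGPAGAPGRLGPAGPPGAVGPPGADGSDGLSGEPGKP
GPPGEPGPQGLLGPFGPTGPVGKFGEPGKPGLQGLNGSQGDVGSQGPMGLPGAVGPPGKP
GSMGKPGDNGRPGLPGEVGDQGLPGRFGPPGRSGPPGLQGPPGPDGPPGPTGPQGLPGAS
GETGETGSNGPSGPDGLFGLPGEQGPMGEPGATGRPGEDGPPGASGAFGLNGPPGPVGRP
GSPGPDGPVGADGEDGELGPPGKLGAPGDPGAPGEPGRFGPPGKPGPMGRFGAPGPSGPP
GKVGPVGRVGPMGLVGKTGSLGPVGPTGPPGKPGRQGELGPDGPAGLAGEFGPVGLPGPS
GLLGPAGPTGLPGREGLPGPPGAPGETGEQGPQGRMGPPGLNGPVGDPGASGPFGDEGPQ
GPQGPPGSSGSLGPQGKLGDSGATGKAGAPGPVGAPGRDGAVGPSGPPGPFGLQGKAGPF
GENGANGPPGAEGPVGAPGSPGAMGAFGEPGDTGAQGLQGPFGAPGLLGEVGLPGEDGKS
GKPGRFGAFGDMGPAGSPGAPGEEGAPGSPGDPGEPGSDGDEGLFGAPGDFGPNGRPGPT
GRDGAPGRPGPPGKFGSQGLPGRFGLVGPPGELGPMGAQGPSGEPGEPGDVGAPGDQGDP
GRPGPPGPPGAPGRMGPEGSLGPNGPQGKSGLEGEFGPAGLTGPSGAEGLQGPFGDAGAP
GASGPSGPVGPAGPQGAVGPNGEPGDQGAEGALGPPGALGPNGSQGPPGDEGPPGRQGKF
GAPGPPGAMGENGADGASGRPGRQGDFGANGLFGAPGPPGPQGELGPPGKLGKPGPSGPP
GPAGDPGALGETGLQGAPGPVGPLGPPGPPGKPGPQGPPGALGPVGSPGAPGEQGPNGLP
GDPGSEGPPGKFGEAGAPGPQGDQGPMGAPGSEGPTGSNGEPGPPGPPGPPGANGPPGPN
GSLGKPGLLGRAGEQGESGPPGLDGASGPAGLTGKPGAMGPVGAPGAQGPVGRPGPTGRV
GKTGPTGRPGSVGPTGPPGPDGPSGAPGDEGENGDPGDPGPAGPEGPFGSSGDPGPFGDS
GLTGSNGDAMMHSMYELAYLDVDG
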